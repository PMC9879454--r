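# Serialization of pipeline artifacts: dosage tables, truth tables,
# event calls and fluctuation experiments.

#' Write / read a SNP dosage table (counts.tsv)
#'
#' Columns: `chrom`, `pos`, `parental_class`, `count`.
#'
#' @param table a `snp_dosage` data.frame.
#' @param path file path.
#' @export
write_snp_counts <- function(table, path) {
  utils::write.table(
    data.frame(chrom = table$chromosome, pos = table$position,
               parental_class = table$parental_class,
               count = table$read_count),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_snp_counts
#' @export
read_snp_counts <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stopf("failed to parse %s: %s", path, conditionMessage(e))
  )
  need <- c("chrom", "pos", "parental_class", "count")
  if (!all(need %in% names(df))) {
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$pos))
  count <- suppressWarnings(as.integer(df$count))
  bad <- which(is.na(pos) | is.na(count) | count < 0)
  if (length(bad)) stopf("%s line %d: invalid position or count",
                         path, bad[1] + 1L)
  out <- data.frame(
    chromosome = df$chrom, position = pos,
    parental_class = df$parental_class, read_count = count,
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_dosage", "data.frame")
  out
}

#' Write / read a truth table (truth.tsv)
#'
#' @param truth truth data.frame from [simulate_isolate()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Write event calls as JSON and a TSV summary
#'
#' @param calls call data.frame from [call_events()].
#' @param json_path path for events.json (`NULL` to skip).
#' @param tsv_path path for events.tsv (`NULL` to skip).
#' @export
write_events <- function(calls, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(calls, json_path, auto_unbox = FALSE, digits = NA,
                         na = "null")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(calls)
}

#' @rdname write_events
#' @param path events.json path.
#' @export
read_events <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Write / read a fluctuation experiment (fluctuation.tsv)
#'
#' Columns: `culture_id`, `mutant_count`, `N_t`.
#'
#' @param experiment a `fluctuation_experiment`.
#' @param path file path.
#' @export
write_fluctuation <- function(experiment, path) {
  utils::write.table(
    data.frame(culture_id = seq_along(experiment$counts),
               mutant_count = experiment$counts,
               N_t = experiment$N_t),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_fluctuation
#' @export
read_fluctuation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(
    list(counts = as.integer(df$mutant_count), N_t = df$N_t[1],
         rate_true = NA_real_),
    class = "fluctuation_experiment"
  )
}
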