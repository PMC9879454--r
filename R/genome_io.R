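# On-disk representation of a diploid genome:
#   chromosomes.tsv  name, length, cen_start, cen_end
#   ty.bed           BED6+2 (0-based half-open; strand + = Watson, - = Crick;
#                    extra columns: homolog, family)
#   snps.tsv         chrom, pos, w_allele, y_allele
# Internal coordinates are 1-based inclusive; conversion happens here only.

#' Write a diploid genome to a directory
#'
#' @param genome a `diploid_genome`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    genome$chromosomes, file.path(dir, "chromosomes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  ty <- genome$ty_elements
  bed <- data.frame(
    chrom = ty$chromosome,
    start = ty$start - 1L,              # to 0-based half-open
    end = ty$end,
    name = ty$id,
    score = 0L,
    strand = ifelse(ty$orientation == "Watson", "+", "-"),
    homolog = ty$homolog,
    family = ty$family,
    stringsAsFactors = FALSE
  )
  utils::write.table(
    bed, file.path(dir, "ty.bed"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  sn <- genome$snps
  utils::write.table(
    data.frame(chrom = sn$chromosome, pos = sn$position,
               w_allele = sn$w_allele, y_allele = sn$y_allele),
    file.path(dir, "snps.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  meta <- list(dsb_offset = genome$dsb_offset, profile = genome$profile)
  jsonlite::write_json(meta, file.path(dir, "genome.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a diploid genome from a directory
#'
#' Inverse of [write_genome()]; `read_genome(write_genome(g, d))` is the
#' identity on all fields. Malformed rows produce an error naming the file
#' and line.
#'
#' @param dir directory containing `chromosomes.tsv`, `ty.bed`, `snps.tsv`
#'   and `genome.json`.
#' @return a `diploid_genome`.
#' @export
read_genome <- function(dir) {
  path <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stopf("missing genome file '%s'", p)
    p
  }
  chroms <- utils::read.table(
    path("chromosomes.tsv"), header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  )
  bed <- utils::read.table(
    path("ty.bed"), header = FALSE, sep = "\t", stringsAsFactors = FALSE,
    col.names = c("chrom", "start", "end", "name", "score", "strand",
                  "homolog", "family")
  )
  bad <- which(bed$end <= bed$start)
  if (length(bad)) {
    stopf("%s line %d: end <= start", file.path(dir, "ty.bed"), bad[1])
  }
  bad <- which(!bed$chrom %in% chroms$name)
  if (length(bad)) {
    stopf("%s line %d: unknown chromosome '%s'",
          file.path(dir, "ty.bed"), bad[1], bed$chrom[bad[1]])
  }
  ty <- data.frame(
    id = bed$name, family = bed$family,
    orientation = ifelse(bed$strand == "+", "Watson", "Crick"),
    homolog = bed$homolog, chromosome = bed$chrom,
    start = as.integer(bed$start + 1L),  # back to 1-based inclusive
    end = as.integer(bed$end),
    has_cas9_target = bed$family == "Ty1",
    stringsAsFactors = FALSE
  )
  sn <- utils::read.table(
    path("snps.tsv"), header = TRUE, sep = "\t", stringsAsFactors = FALSE
  )
  bad <- which(!sn$chrom %in% chroms$name)
  if (length(bad)) {
    stopf("%s line %d: unknown chromosome '%s'",
          file.path(dir, "snps.tsv"), bad[1] + 1L, sn$chrom[bad[1]])
  }
  meta <- jsonlite::read_json(path("genome.json"))
  genome <- structure(
    list(
      chromosomes = chroms,
      snps = data.frame(
        chromosome = sn$chrom, position = as.integer(sn$pos),
        w_allele = sn$w_allele, y_allele = sn$y_allele,
        stringsAsFactors = FALSE
      ),
      ty_elements = ty,
      dsb_offset = as.integer(meta$dsb_offset),
      profile = meta$profile
    ),
    class = "diploid_genome"
  )
  validate_genome(genome)
  genome
}
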