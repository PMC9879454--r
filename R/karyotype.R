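# Karyotype model: each chromosome molecule is an ordered list of segments of
# parental material. A segment is a stretch of one homolog's chromosome in
# parental coordinates, traversed forward or reverse. Per-SNP copy numbers of
# each parental allele follow by interval arithmetic over the segments.

new_segment <- function(homolog, chromosome, start, end,
                        orientation = "forward") {
  stopifnot(end >= start)
  data.frame(
    homolog = homolog, chromosome = chromosome,
    start = as.integer(start), end = as.integer(end),
    orientation = orientation, stringsAsFactors = FALSE
  )
}

new_molecule <- function(name, segments, circular = FALSE) {
  list(name = name, segments = segments, circular = circular)
}

#' Baseline karyotype of a diploid genome
#'
#' Two intact molecules per chromosome, one per parental homolog class
#' (`W` and `Y`).
#'
#' @param genome a `diploid_genome`.
#' @return an object of class `karyotype`.
#' @export
baseline_karyotype <- function(genome) {
  mols <- list()
  for (i in seq_len(nrow(genome$chromosomes))) {
    cd <- genome$chromosomes[i, ]
    for (homolog in c("W", "Y")) {
      mols[[length(mols) + 1L]] <- new_molecule(
        sprintf("%s_%s", cd$name, homolog),
        new_segment(homolog, cd$name, 1L, cd$length)
      )
    }
  }
  structure(list(genome = genome, molecules = mols), class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("<karyotype> %d molecules over %d chromosomes\n",
              length(x$molecules), nrow(x$genome$chromosomes)))
  for (m in x$molecules) {
    cat(sprintf(
      "  %s%s: %d segment(s), %d centromere(s)\n",
      m$name, if (isTRUE(m$circular)) " (circular)" else "",
      nrow(m$segments), molecule_cen_count(m, x$genome)
    ))
  }
  invisible(x)
}

rev_segments <- function(segs) {
  segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  segs$orientation <- ifelse(segs$orientation == "forward",
                             "reverse", "forward")
  rownames(segs) <- NULL
  segs
}

# Split one segment immediately before parental position `pos` in traversal
# order. Returns list(pre=, post=) of 0-1 row segment data.frames.
.split_segment <- function(seg, pos) {
  if (seg$orientation == "forward") {
    pre <- if (pos > seg$start) {
      new_segment(seg$homolog, seg$chromosome, seg$start, pos - 1L)
    }
    post <- new_segment(seg$homolog, seg$chromosome, pos, seg$end)
  } else {
    pre <- if (pos < seg$end) {
      new_segment(seg$homolog, seg$chromosome, pos + 1L, seg$end, "reverse")
    }
    post <- new_segment(seg$homolog, seg$chromosome, seg$start, pos, "reverse")
  }
  list(pre = pre, post = post)
}

# Split a molecule's segment list at the first segment matching
# (homolog, chromosome) that covers parental position `pos`.
# Returns list(pre=, post=) segment data.frames, or NULL if not found.
split_molecule <- function(mol, homolog, chromosome, pos) {
  segs <- mol$segments
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$homolog == homolog && s$chromosome == chromosome &&
        s$start <= pos && pos <= s$end) {
      sp <- .split_segment(s, pos)
      pre <- rbind(
        if (i > 1) segs[seq_len(i - 1L), , drop = FALSE],
        sp$pre
      )
      post <- rbind(
        sp$post,
        if (i < nrow(segs)) segs[seq(i + 1L, nrow(segs)), , drop = FALSE]
      )
      if (is.null(pre)) {
        pre <- segs[0, , drop = FALSE]
      }
      rownames(pre) <- rownames(post) <- NULL
      return(list(pre = pre, post = post))
    }
  }
  NULL
}

# Extract the contiguous molecule block whose parental coordinates lie in
# [lo, hi] for (homolog, chromosome): boundary-splits partially overlapping
# segments, then requires the in-range segments to be contiguous in molecule
# order. Returns list(pre=, block=, post=) or errors.
extract_block <- function(mol, homolog, chromosome, lo, hi) {
  segs <- mol$segments
  out <- segs[0, , drop = FALSE]
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$homolog == homolog && s$chromosome == chromosome &&
        s$start <= hi && s$end >= lo) {
      pieces <- if (s$start < lo) .split_in_order(s, lo) else s
      expanded <- list()
      for (j in seq_len(nrow(pieces))) {
        p <- pieces[j, ]
        if (p$start <= hi && p$end > hi && p$end >= p$start) {
          expanded[[length(expanded) + 1L]] <- .split_in_order(p, hi + 1L)
        } else {
          expanded[[length(expanded) + 1L]] <- p
        }
      }
      out <- rbind(out, do.call(rbind, expanded))
    } else {
      out <- rbind(out, s)
    }
  }
  rownames(out) <- NULL
  inside <- out$homolog == homolog & out$chromosome == chromosome &
    out$start >= lo & out$end <= hi
  idx <- which(inside)
  if (!length(idx)) stopf("block [%d, %d] not present on molecule", lo, hi)
  if (any(diff(idx) != 1L)) {
    stopf("block [%d, %d] is not contiguous on molecule", lo, hi)
  }
  list(
    pre = out[seq_len(min(idx) - 1L), , drop = FALSE],
    block = out[idx, , drop = FALSE],
    post = out[seq(max(idx) + 1L, length.out = nrow(out) - max(idx)), ,
               drop = FALSE]
  )
}

# merge consecutive segments that are parentally adjacent with the same
# homolog, chromosome and orientation (normal form after block operations)
normalize_segments <- function(segs) {
  if (nrow(segs) < 2) return(segs)
  out <- segs[1, , drop = FALSE]
  for (i in seq(2, nrow(segs))) {
    s <- segs[i, ]
    last <- out[nrow(out), ]
    mergeable <- s$homolog == last$homolog &&
      s$chromosome == last$chromosome &&
      s$orientation == last$orientation &&
      ((s$orientation == "forward" && s$start == last$end + 1L) ||
         (s$orientation == "reverse" && s$end == last$start - 1L))
    if (mergeable) {
      out$start[nrow(out)] <- min(last$start, s$start)
      out$end[nrow(out)] <- max(last$end, s$end)
    } else {
      out <- rbind(out, s)
    }
  }
  rownames(out) <- NULL
  out
}

# split one segment at parental position pos, returning both pieces in
# MOLECULE traversal order
.split_in_order <- function(s, pos) {
  sp <- .split_segment(s, pos)
  rbind(sp$pre, sp$post)
}

# Index of the first molecule covering parental (homolog, chromosome, pos).
find_molecule <- function(k, homolog, chromosome, pos) {
  for (i in seq_along(k$molecules)) {
    segs <- k$molecules[[i]]$segments
    hit <- segs$homolog == homolog & segs$chromosome == chromosome &
      segs$start <= pos & segs$end >= pos
    if (any(hit)) return(i)
  }
  NA_integer_
}

#' Number of centromeres carried by a molecule
#'
#' A segment contributes a centromere when it fully contains the centromere
#' span of its source chromosome.
#'
#' @param mol a molecule from a [karyotype].
#' @param genome the provenance `diploid_genome`.
#' @return integer count; 0 flags an acentric molecule, >= 2 a dicentric.
#' @export
molecule_cen_count <- function(mol, genome) {
  segs <- mol$segments
  m <- match(segs$chromosome, genome$chromosomes$name)
  sum(segs$start <= genome$chromosomes$cen_start[m] &
        segs$end >= genome$chromosomes$cen_end[m])
}

#' Check that every molecule of a karyotype is monocentric
#'
#' Dicentric or acentric molecules must be resolved (or dropped) before any
#' read-depth signal is synthesized from the karyotype; biologically they are
#' selected against through breakage-fusion cycles.
#'
#' @param k a `karyotype`.
#' @return `k` invisibly; errors name the first offending molecule.
#' @export
assert_monocentric <- function(k) {
  for (m in k$molecules) {
    n <- molecule_cen_count(m, k$genome)
    if (n != 1L) {
      stopf("molecule %s has %d centromeres; resolve before synthesis",
            m$name, n)
    }
  }
  invisible(k)
}

#' Per-SNP parental copy numbers of a karyotype
#'
#' Sums, for every heterozygous SNP of the provenance genome, the number of
#' molecule segments of each parental class covering the SNP position.
#'
#' @param k a `karyotype`.
#' @return data.frame with `chromosome`, `position`, `w_copies`, `y_copies`.
#' @export
copy_number_profile <- function(k) {
  sn <- k$genome$snps
  w <- integer(nrow(sn))
  y <- integer(nrow(sn))
  key <- paste(sn$chromosome)
  for (mol in k$molecules) {
    segs <- mol$segments
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      hit <- which(key == s$chromosome &
                     sn$position >= s$start & sn$position <= s$end)
      if (!length(hit)) next
      if (s$homolog == "W") w[hit] <- w[hit] + 1L else y[hit] <- y[hit] + 1L
    }
  }
  data.frame(
    chromosome = sn$chromosome, position = sn$position,
    w_copies = w, y_copies = y, stringsAsFactors = FALSE
  )
}

# Adjacencies between consecutive segments that are not adjacent in the
# parental genome (novel junctions), plus circular closure if applicable.
molecule_junctions <- function(mol) {
  segs <- mol$segments
  n <- nrow(segs)
  if (n < 1) return(NULL)
  ends <- function(i) {
    s <- segs[i, ]
    if (s$orientation == "forward") c(head = s$start, tail = s$end)
    else c(head = s$end, tail = s$start)
  }
  pairs <- if (isTRUE(mol$circular)) cbind(seq_len(n), c(seq_len(n)[-1], 1L))
    else cbind(seq_len(n - 1L), seq_len(n)[-1])
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    a <- segs[i, ]; b <- segs[j, ]
    tail_a <- ends(i)[["tail"]]
    head_b <- ends(j)[["head"]]
    natural <- a$homolog == b$homolog && a$chromosome == b$chromosome &&
      a$orientation == b$orientation &&
      ((a$orientation == "forward" && head_b == tail_a + 1L) ||
         (a$orientation == "reverse" && head_b == tail_a - 1L))
    if (!natural) {
      out[[length(out) + 1L]] <- data.frame(
        left_homolog = a$homolog, left_chromosome = a$chromosome,
        left_pos = tail_a,
        right_homolog = b$homolog, right_chromosome = b$chromosome,
        right_pos = head_b, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) NULL else do.call(rbind, out)
}

#' Serialize / deserialize a karyotype as JSON
#'
#' Molecules are written as ordered segment records
#' (homolog, chromosome, start, end, orientation). The genome itself is not
#' embedded; supply it again when reading.
#'
#' @param k a `karyotype`.
#' @param path output JSON file.
#' @export
write_karyotype <- function(k, path) {
  mols <- lapply(k$molecules, function(m) {
    list(name = m$name, circular = isTRUE(m$circular),
         segments = m$segments)
  })
  jsonlite::write_json(mols, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param genome the provenance `diploid_genome`.
#' @rdname write_karyotype
#' @export
read_karyotype <- function(path, genome) {
  mols <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  molecules <- lapply(seq_len(nrow(mols)), function(i) {
    segs <- mols$segments[[i]]
    segs$start <- as.integer(segs$start)
    segs$end <- as.integer(segs$end)
    new_molecule(mols$name[i], segs, isTRUE(mols$circular[i]))
  })
  structure(list(genome = genome, molecules = molecules),
            class = "karyotype")
}
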