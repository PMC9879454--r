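# Shared fixtures. The mini genome is deterministic for its seed and
# expensive enough to be worth caching across test files.

.fixture_env <- new.env(parent = emptyenv())

full_genome <- function(seed = 1) {
  key <- paste0("full_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- default_hybrid_genome(seed, profile = "full")
  }
  .fixture_env[[key]]
}

mini_genome <- function(seed = 1) {
  key <- paste0("mini_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- default_hybrid_genome(seed, profile = "mini")
  }
  .fixture_env[[key]]
}

# hand-built tiny genome for enumeration tests: explicit chromosomes, SNPs
# and Ty1 placement
toy_genome <- function(ty_table, n_chroms = 4, chrom_len = 200000L,
                       snp_every = 5000L) {
  chroms <- data.frame(
    name = as.character(utils::as.roman(seq_len(n_chroms))),
    length = chrom_len,
    cen_start = as.integer(chrom_len / 2),
    cen_end = as.integer(chrom_len / 2 + 120),
    stringsAsFactors = FALSE
  )
  snps <- do.call(rbind, lapply(chroms$name, function(ch) {
    pos <- seq(snp_every, chrom_len - snp_every, by = snp_every)
    keep <- rep(TRUE, length(pos))
    tysub <- ty_table[ty_table$chromosome == ch, , drop = FALSE]
    for (i in seq_len(nrow(tysub))) {
      keep <- keep & !(pos >= tysub$start[i] & pos <= tysub$end[i])
    }
    data.frame(chromosome = ch, position = pos[keep],
               w_allele = "A", y_allele = "G", stringsAsFactors = FALSE)
  }))
  g <- structure(
    list(chromosomes = chroms, snps = snps, ty_elements = ty_table,
         dsb_offset = 2180L, profile = "toy"),
    class = "diploid_genome"
  )
  validate_genome(g)
  g
}

toy_ty <- function(id, chromosome, start, homolog = "W",
                   orientation = "Watson", family = "Ty1", span = 6000L) {
  data.frame(
    id = id, family = family, orientation = orientation, homolog = homolog,
    chromosome = chromosome, start = as.integer(start),
    end = as.integer(start + span - 1L),
    has_cas9_target = family == "Ty1", stringsAsFactors = FALSE
  )
}

# brute-force per-SNP copy number oracle: explicit membership test of every
# SNP against every segment of every molecule
oracle_profile <- function(k) {
  sn <- k$genome$snps
  w <- integer(nrow(sn)); y <- integer(nrow(sn))
  for (i in seq_len(nrow(sn))) {
    for (mol in k$molecules) {
      for (j in seq_len(nrow(mol$segments))) {
        s <- mol$segments[j, ]
        if (s$chromosome == sn$chromosome[i] &&
            s$start <= sn$position[i] && sn$position[i] <= s$end) {
          if (s$homolog == "W") w[i] <- w[i] + 1L else y[i] <- y[i] + 1L
        }
      }
    }
  }
  data.frame(chromosome = sn$chromosome, position = sn$position,
             w_copies = w, y_copies = y, stringsAsFactors = FALSE)
}

# noise-free dosage table: read counts exactly proportional to copy number
exact_counts <- function(k, depth = 40) {
  prof <- copy_number_profile(k)
  out <- rbind(
    data.frame(chromosome = prof$chromosome, position = prof$position,
               parental_class = "W",
               read_count = as.integer(depth / 2 * prof$w_copies)),
    data.frame(chromosome = prof$chromosome, position = prof$position,
               parental_class = "Y",
               read_count = as.integer(depth / 2 * prof$y_copies))
  )
  class(out) <- c("snp_dosage", "data.frame")
  out
}
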