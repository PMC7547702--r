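# Independent oracles used by the tests. These deliberately avoid the
# package's joint-distribution propagation, interval-sweep clustering and
# Biostrings alignment code paths.

# ---- carbon-tracing MID oracle -------------------------------------------
# Because tracer substrates are labelled independently per position and atom
# transitions are bijections, every carbon of every compound traces back to a
# single tracer carbon. The oracle recovers each position's enrichment by
# following transitions backwards, then enumerates all 2^n labelling patterns
# of independent Bernoulli carbons.

oracle_position_enrichments <- function(model, reaction_ids, tracer, compound) {
  roots <- names(tracer$enrichments)
  producer <- list()
  for (rid in reaction_ids) {
    rx <- model$reactions[[rid]]
    for (cid in names(rx$stoich)) {
      if (rx$stoich[[cid]] > 0 && model$compounds[[cid]]$n_carbons > 0 &&
          !(cid %in% roots)) {
        producer[[cid]] <- rid
      }
    }
  }
  enrich1 <- function(cid, idx) {
    if (cid %in% roots) {
      n <- model$compounds[[cid]]$n_carbons
      return(rep_len(as.numeric(tracer$enrichments[[cid]]), n)[idx])
    }
    rx <- model$reactions[[producer[[cid]]]]
    tr <- rx$transitions
    row <- tr[tr$product_compound == cid & tr$product_instance == 1L &
              tr$product_index == idx, , drop = FALSE]
    enrich1(row$source_compound, row$source_index)
  }
  n <- model$compounds[[compound]]$n_carbons
  vapply(seq_len(n), function(i) enrich1(compound, i), numeric(1))
}

oracle_mid <- function(model, reaction_ids, tracer, compound) {
  e <- oracle_position_enrichments(model, reaction_ids, tracer, compound)
  n <- length(e)
  mid <- numeric(n + 1)
  for (k in 0:(2^n - 1)) {
    bits <- bitwAnd(bitwShiftR(k, seq_len(n) - 1L), 1L)
    p <- prod(ifelse(bits == 1, e, 1 - e))
    mid[sum(bits) + 1] <- mid[sum(bits) + 1] + p
  }
  mid
}

# ---- pairwise-chain clustering oracle ------------------------------------
# Brute-force single linkage: connected components of the graph whose edges
# join hits on the same subject with inter-interval gap <= window.

oracle_cluster_membership <- function(hits, window_bp) {
  n <- nrow(hits)
  if (n == 0) return(integer(0))
  gap <- function(i, j) {
    if (hits$subject_id[i] != hits$subject_id[j]) return(Inf)
    lo <- max(hits$subject_start[i], hits$subject_start[j])
    hi <- min(hits$subject_end[i], hits$subject_end[j])
    if (lo <= hi + 1) 0 else lo - hi - 1
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && gap(i, j) <= window_bp) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# ---- quadratic affine-gap Smith-Waterman oracle --------------------------
# Gotoh DP, score only; gap of length L costs open + L * ext (the same
# convention as the implementation under test).

oracle_sw_score <- function(a, b, submat, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- submat[a[i], b[j]]
      M[i + 1, j + 1] <- max(0,
                             M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# six frames of a nucleotide string, as plain character AA strings
oracle_six_frames <- function(nt) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  out <- list()
  for (src in list(fwd = nt, rev = rc)) {
    for (off in 0:2) {
      n_codons <- (nchar(src) - off) %/% 3
      if (n_codons < 1) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(src, off + 1, off + 3 * n_codons)),
        if.fuzzy.codon = "X", no.init.codon = TRUE)))
      out[[length(out) + 1]] <- chartr("*", "X", aa)
    }
  }
  out
}

# random protein / naive back-translation for alignment fixtures
random_protein <- function(len) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  paste0("M", paste(sample(aa, len - 1, replace = TRUE), collapse = ""))
}

back_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  codons_by_aa <- split(names(gc), gc)
  aas <- strsplit(protein, "")[[1]]
  paste(vapply(aas, function(a) sample(codons_by_aa[[a]], 1), character(1)),
        collapse = "")
}

# random valid MID under the current RNG state
random_mid <- function(n_carbons) {
  v <- stats::runif(n_carbons + 1)
  v / sum(v)
}

# a tiny two-reaction cyclic model written to a temp file
write_cyclic_model <- function() {
  txt <- '
compounds:
  - {id: cpdA, name: a, n_carbons: 1, carbon_roles: [c]}
  - {id: cpdB, name: b, n_carbons: 1, carbon_roles: [c]}
reactions:
  - id: R1
    name: a to b
    stoich: {cpdA: -1, cpdB: 1}
    atp_delta: 0
    electron_pairs: 0
    transitions: ["cpdB.1 <- cpdA.1"]
  - id: R2
    name: b to a
    stoich: {cpdB: -1, cpdA: 1}
    atp_delta: 0
    electron_pairs: 0
    transitions: ["cpdA.1 <- cpdB.1"]
variants: []
networks:
  loop: [R1, R2]
'
  path <- tempfile(fileext = ".yaml")
  writeLines(txt, path)
  path
}
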