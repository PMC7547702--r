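#' Plan a set of synthetic fixture genomes
#'
#' Describes seeded fixture genomes with planted pathway content for
#' exercising the genome screen end to end: per genome a planted route
#' (`"A"` = glycine reductase, `"B"` = serine, `"both"`, `"none"`), an operon
#' intactness scenario (`"full"`, `"missing"` = route-defining complex below
#' its minimum gene count, `"split"` = route-defining complex split by a gap
#' of exactly `window_bp + 1`, `"split_contig"` = split across two contigs),
#' and a number of decoy genes. Scenarios default to cycling through all
#' route x intactness combinations.
#'
#' @param n_genomes Number of genomes (default 50).
#' @param seed RNG seed; same seed gives byte-identical outputs.
#' @param window_bp Co-occurrence window probed by the split scenarios.
#' @param intergenic_gap Two-element integer vector: uniform bounds (bp) for
#'   gaps between genes inside an operon.
#' @param n_decoys Two-element integer vector: uniform bounds for the decoy
#'   gene count per genome.
#' @param scenarios Optional `data.frame` with columns `route` and
#'   `intactness` overriding the default cycle (recycled to `n_genomes`).
#' @param emit_sequences Generate nucleotide sequences (default TRUE); hit
#'   tables and truth are position-exact either way.
#' @return A `genome_plan` object.
#' @export
genome_plan <- function(n_genomes = 50, seed = 1, window_bp = 20000,
                        intergenic_gap = c(50, 500), n_decoys = c(5, 15),
                        scenarios = NULL, emit_sequences = TRUE) {
  stopifnot(n_genomes >= 1, length(intergenic_gap) == 2,
            intergenic_gap[1] >= 0, intergenic_gap[2] >= intergenic_gap[1])
  if (is.null(scenarios)) {
    routes <- c("A", "B", "both", "none")
    intact <- c("full", "missing", "split", "split_contig")
    idx <- seq_len(n_genomes) - 1
    scenarios <- data.frame(
      route = routes[idx %% 4 + 1],
      intactness = intact[(idx %/% 4) %% 4 + 1],
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(all(c("route", "intactness") %in% names(scenarios)))
    scenarios <- scenarios[rep_len(seq_len(nrow(scenarios)), n_genomes), ,
                           drop = FALSE]
  }
  scenarios$intactness[scenarios$route == "none"] <- "full"
  structure(list(n_genomes = n_genomes, seed = seed, window_bp = window_bp,
                 intergenic_gap = as.integer(intergenic_gap),
                 n_decoys = as.integer(n_decoys),
                 scenarios = scenarios, emit_sequences = emit_sequences),
            class = "genome_plan")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1, replace = TRUE), collapse = ""))
}

back_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  codons_by_aa <- split(names(gc), gc)
  aas <- strsplit(protein, "")[[1]]
  body <- paste(vapply(aas, function(a) sample(codons_by_aa[[a]], 1),
                       character(1)), collapse = "")
  paste0(body, sample(codons_by_aa[["*"]], 1))
}

# percent identity of a global alignment, for decoy verification
global_pid <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1")
}

#' Generate fixture genomes, hit tables and a truth table
#'
#' Deterministic under the plan's seed. Planted genes are random-codon
#' back-translations of random protein queries; decoys are shuffled proteins
#' verified at generation time to fall below 25% global identity to every
#' query. The hit table contains one clean hit per planted gene at its true
#' coordinates, plus spurious hits to rule genes that fail the identity or
#' e-value threshold (and must therefore not affect the screen).
#'
#' @param plan A [genome_plan()].
#' @param ruleset The ruleset whose genes are planted (default shipped rGly
#'   rules).
#' @param out_dir Optional directory; when given, writes `genomes.fasta`,
#'   `queries.fasta`, `hits.tsv`, `truth.csv` and `genome_map.csv`.
#' @return List with `genomes` (named character vector of sequences, or NULL),
#'   `hits` (hit `data.frame`), `truth` (`data.frame` with the intended
#'   screen result per genome, under `require_fdh` mode), `genome_map`,
#'   `queries` (named character vector of proteins) and `plan`.
#' @export
make_genomes <- function(plan, ruleset = load_ruleset(), out_dir = NULL) {
  stopifnot(inherits(plan, "genome_plan"))
  set.seed(plan$seed)
  window <- plan$window_bp

  # gene roster: complex genes plus the single-gene roles
  complex_genes <- lapply(ruleset$complexes, `[[`, "gene_ids")
  single_genes <- ruleset$singles
  all_genes <- c(unlist(complex_genes, use.names = FALSE),
                 unname(single_genes))

  queries <- vapply(all_genes, function(g) random_protein(sample(120:250, 1)),
                    character(1))

  # decoy pool: shuffled queries, verified < 25% global identity to all queries
  n_pool <- 25
  decoy_pool <- character(0)
  while (length(decoy_pool) < n_pool) {
    src <- queries[[sample(length(queries), 1)]]
    cand <- paste(sample(strsplit(src, "")[[1]]), collapse = "")
    ok <- all(vapply(queries, function(q) global_pid(cand, q) < 25, logical(1)))
    if (ok) decoy_pool <- c(decoy_pool, cand)
  }
  names(decoy_pool) <- paste0("decoy_", seq_along(decoy_pool))

  core_complexes <- c("FDH_1.17.2.3", ruleset$gcs)
  gr_name <- ruleset$route_A$complex

  hits <- list()
  truth <- list()
  map_rows <- list()
  sequences <- list()

  for (i in seq_len(plan$n_genomes)) {
    gid <- sprintf("synthgenome_%03d", i)
    route <- plan$scenarios$route[i]
    intact <- plan$scenarios$intactness[i]

    # blocks: list of (subject, genes); a block's genes co-occur tightly
    blocks <- list()
    add_block <- function(subject, genes) {
      blocks[[length(blocks) + 1]] <<- list(subject = subject, genes = genes)
    }
    subj_main <- if (intact == "split_contig") paste0(gid, "_c1") else gid
    subj_alt <- if (intact == "split_contig") paste0(gid, "_c2") else gid

    planted_single <- character(0)
    if (route %in% c("A", "B", "both")) {
      add_block(subj_main, complex_genes[["FDH_1.17.2.3"]])
      planted_single <- c("FTL", "MTCD")

      gcs_genes <- complex_genes[[ruleset$gcs]]
      gr_genes <- complex_genes[[gr_name]]

      degrade_b <- route %in% c("B")  # in "both", degrade the GR operon only
      if (route %in% c("A", "both")) {
        planted_single <- c(planted_single, "ACK", if (i %% 2 == 0) "PTA")
        gr_block <- switch(intact,
          full = list(gr_genes),
          missing = list(gr_genes[1:4]),                 # 4 < min 5
          split = list(gr_genes[1:4], gr_genes[5:7]),    # 4 and 3, both < 5
          split_contig = list(gr_genes[1:4], gr_genes[5:7]))
      } else {
        gr_block <- NULL
      }
      if (degrade_b && intact != "full") {
        if (intact == "missing") {
          planted_single <- setdiff(planted_single, character(0))
          # drop SDA below: route B needs both SHMT and SDA
          gcs_block <- list(gcs_genes)
          b_single <- "SHMT"
        } else {
          # split the GCS (2 + 2, both < min 3): kills the pathway core
          gcs_block <- list(gcs_genes[1:2], gcs_genes[3:4])
          b_single <- c("SHMT", "SDA")
        }
      } else {
        gcs_block <- list(gcs_genes)
        b_single <- c("SHMT", "SDA")
      }
      if (route %in% c("B", "both")) {
        planted_single <- c(planted_single,
                            if (route == "both") c("SHMT", "SDA") else b_single)
      }

      for (b in seq_along(gcs_block)) {
        add_block(if (b == 1) subj_main else subj_alt, gcs_block[[b]])
      }
      if (!is.null(gr_block)) {
        for (b in seq_along(gr_block)) {
          add_block(if (b == 1) subj_main else subj_alt, gr_block[[b]])
        }
      }
      add_block(subj_main, unname(single_genes[unique(planted_single)]))
    }
    n_dec <- sample(plan$n_decoys[1]:plan$n_decoys[2], 1)
    dec_ids <- sample(names(decoy_pool), n_dec, replace = FALSE)
    add_block(subj_main, dec_ids)

    # lay out blocks along each subject; same-subject "split" blocks are
    # separated by a gap of exactly window + 1, other blocks by > window
    placements <- list()
    cursor <- stats::setNames(as.list(rep(1000L, 2)), c(subj_main, subj_alt))
    prev_end <- stats::setNames(as.list(rep(NA_integer_, 2)),
                                c(subj_main, subj_alt))
    for (bi in seq_along(blocks)) {
      blk <- blocks[[bi]]
      if (length(blk$genes) == 0) next
      subj <- blk$subject
      is_split_partner <- intact == "split" && bi > 1 &&
        identical(blocks[[bi - 1]]$subject, subj) &&
        any(blk$genes %in% unlist(complex_genes)) &&
        any(blocks[[bi - 1]]$genes %in% unlist(complex_genes)) &&
        length(intersect(
          names(which(vapply(complex_genes, function(g)
            any(blk$genes %in% g), logical(1)))),
          names(which(vapply(complex_genes, function(g)
            any(blocks[[bi - 1]]$genes %in% g), logical(1)))))) > 0
      if (is_split_partner) {
        # gap of exactly window + 1 from the previous block's last gene
        cursor[[subj]] <- prev_end[[subj]] + window + 2L
      } else if (!is.na(prev_end[[subj]])) {
        cursor[[subj]] <- prev_end[[subj]] + window + 5000L +
          sample.int(5000L, 1)
      }
      pos <- cursor[[subj]]
      for (g in blk$genes) {
        prot <- if (g %in% names(queries)) queries[[g]] else decoy_pool[[g]]
        glen <- 3L * (nchar(prot) + 1L)
        placements[[length(placements) + 1]] <- list(
          gene = g, subject = subj, start = pos, end = pos + glen - 1L,
          strand = if (stats::runif(1) < 0.3) "-" else "+")
        pos <- pos + glen +
          sample(plan$intergenic_gap[1]:plan$intergenic_gap[2], 1)
      }
      prev_end[[subj]] <- placements[[length(placements)]]$end
    }

    subjects <- unique(vapply(placements, `[[`, character(1), "subject"))
    for (s in subjects) {
      map_rows[[length(map_rows) + 1]] <-
        data.frame(subject_id = s, genome = gid, stringsAsFactors = FALSE)
    }

    # clean hits for planted (non-decoy) genes
    for (pl in placements) {
      if (startsWith(pl$gene, "decoy_")) next
      qlen <- nchar(queries[[pl$gene]])
      hits[[length(hits) + 1]] <- data.frame(
        query_gene = pl$gene, subject_id = pl$subject,
        percent_identity = round(stats::runif(1, 80, 98), 1),
        align_length = qlen, mismatches = sample.int(20L, 1),
        gap_opens = 0L, query_start = 1L, query_end = qlen,
        subject_start = pl$start, subject_end = pl$end,
        e_value = 10^(-stats::runif(1, 20, 80)),
        bit_score = round(stats::runif(1, 100, 500), 1),
        strand = pl$strand, stringsAsFactors = FALSE)
    }
    # spurious sub-threshold hits carrying real rule-gene names
    n_spur <- sample(3:8, 1)
    for (k in seq_len(n_spur)) {
      g <- sample(all_genes, 1)
      qlen <- nchar(queries[[g]])
      below_identity <- stats::runif(1) < 0.5
      spur_start <- sample.int(50000L, 1)
      hits[[length(hits) + 1]] <- data.frame(
        query_gene = g, subject_id = subj_main,
        percent_identity = if (below_identity)
          round(stats::runif(1, 10, 24.9), 1) else
          round(stats::runif(1, 30, 60), 1),
        align_length = qlen, mismatches = sample.int(50L, 1),
        gap_opens = 1L, query_start = 1L, query_end = qlen,
        subject_start = spur_start,
        subject_end = spur_start + 300L,
        e_value = if (below_identity) 10^(-stats::runif(1, 5, 20))
                  else 10^(stats::runif(1, -3.9, 0)),
        bit_score = round(stats::runif(1, 20, 40), 1),
        strand = "+", stringsAsFactors = FALSE)
    }

    # ---- truth, from the planted layout (independent of the hit pipeline) --
    planted_blocks <- lapply(blocks, function(b) b$genes)
    complex_truth <- vapply(names(ruleset$complexes), function(nm) {
      rule <- ruleset$complexes[[nm]]
      any(vapply(planted_blocks, function(g)
        length(intersect(g, rule$gene_ids)) >= rule$min_detected, logical(1)))
    }, logical(1))
    single_truth <- vapply(names(single_genes), function(role) {
      single_genes[[role]] %in% unlist(planted_blocks)
    }, logical(1))
    fdh_t <- any(complex_truth[ruleset$fdh_complexes])
    core_t <- fdh_t && complex_truth[[ruleset$gcs]] &&
      all(single_truth[ruleset$required_singles])
    route_a_t <- core_t && complex_truth[[gr_name]] &&
      any(single_truth[ruleset$route_A$any_of_singles])
    route_b_t <- core_t && all(single_truth[ruleset$route_B])
    truth[[length(truth) + 1]] <- data.frame(
      genome = gid, route_planted = route, intactness = intact,
      fdh_present = fdh_t, gcs_present = unname(complex_truth[[ruleset$gcs]]),
      gr_present = unname(complex_truth[[gr_name]]),
      core_present = core_t, route_A = route_a_t, route_B = route_b_t,
      both_routes = route_a_t && route_b_t, stringsAsFactors = FALSE)

    # ---- sequences ----
    if (plan$emit_sequences) {
      for (s in subjects) {
        pls <- Filter(function(p) p$subject == s, placements)
        total <- max(vapply(pls, `[[`, numeric(1), "end")) + 500L
        seqv <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
        for (pl in pls) {
          prot <- if (pl$gene %in% names(queries)) queries[[pl$gene]]
                  else decoy_pool[[pl$gene]]
          nt <- back_translate(prot)
          if (pl$strand == "-") {
            nt <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(nt)))
          }
          seqv[pl$start:pl$end] <- strsplit(nt, "")[[1]]
        }
        sequences[[s]] <- paste(seqv, collapse = "")
      }
    }
  }

  hits <- do.call(rbind, hits)
  truth <- do.call(rbind, truth)
  genome_map <- unique(do.call(rbind, map_rows))

  out <- list(genomes = if (plan$emit_sequences) unlist(sequences) else NULL,
              hits = hits, truth = truth, genome_map = genome_map,
              queries = queries, plan = plan)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (plan$emit_sequences) {
      writeLines(paste0(">", names(out$genomes), "\n", out$genomes),
                 file.path(out_dir, "genomes.fasta"))
    }
    writeLines(paste0(">", names(queries), "\n", queries),
               file.path(out_dir, "queries.fasta"))
    write_hits_tabular(hits, file.path(out_dir, "hits.tsv"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(genome_map, file.path(out_dir, "genome_map.csv"),
                     row.names = FALSE)
  }
  out
}

#' Plan a synthetic MID dataset
#'
#' @param route True route, `"GR"` or `"serine"`.
#' @param seed RNG seed.
#' @param formate_purity Tracer 13C enrichment of formate (default 0.99, the
#'   labelled-formate purity used in the tracer experiment).
#' @param co2_enrichment 13C enrichment of the CO2 pool (default natural
#'   abundance, 0.0107).
#' @param noise_sd Gaussian noise sd added per MID entry (default 0.02).
#' @param n_replicates Number of replicate datasets (default 3).
#' @param metabolites Metabolite panel (default [amino_acid_panel()]).
#' @return A `mid_plan` object.
#' @export
mid_plan <- function(route = c("GR", "serine"), seed = 1,
                     formate_purity = 0.99, co2_enrichment = 0.0107,
                     noise_sd = 0.02, n_replicates = 3,
                     metabolites = amino_acid_panel()) {
  route <- match.arg(route)
  stopifnot(formate_purity >= 0, formate_purity <= 1, noise_sd >= 0,
            n_replicates >= 1)
  structure(list(route = route, seed = seed, formate_purity = formate_purity,
                 co2_enrichment = co2_enrichment, noise_sd = noise_sd,
                 n_replicates = n_replicates, metabolites = metabolites),
            class = "mid_plan")
}

#' Generate a noisy synthetic MID dataset from a chosen route
#'
#' Computes the route's predicted MIDs under the plan's tracer, then perturbs
#' every fraction with Gaussian noise, truncates at zero and renormalizes so
#' each observed MID remains valid. Deterministic under the plan's seed.
#'
#' @param plan A [mid_plan()].
#' @param model An `rgly_model` (default: shipped model).
#' @param out_file Optional CSV path for the observed MIDs (long dialect with
#'   a `replicate` column).
#' @return List with `observed` (long `data.frame`: `replicate`,
#'   `metabolite`, `m_shift`, `fraction`), `predictions` (noise-free MIDs),
#'   `tracer` and `truth_route`.
#' @export
make_mid_dataset <- function(plan, model = load_pathway_model(),
                             out_file = NULL) {
  stopifnot(inherits(plan, "mid_plan"))
  set.seed(plan$seed)
  tracer <- tracer_config(list(formate = plan$formate_purity,
                               CO2 = plan$co2_enrichment))
  preds <- predict_amino_acid_mids(plan$route, tracer, model,
                                   metabolites = plan$metabolites)
  rows <- list()
  for (r in seq_len(plan$n_replicates)) {
    for (m in names(preds)) {
      v <- as.numeric(preds[[m]])
      noisy <- pmax(0, v + stats::rnorm(length(v), sd = plan$noise_sd))
      if (sum(noisy) == 0) noisy <- v  # degenerate draw: fall back to truth
      noisy <- noisy / sum(noisy)
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, metabolite = m, m_shift = seq_along(v) - 1,
        fraction = noisy, stringsAsFactors = FALSE)
    }
  }
  observed <- do.call(rbind, rows)
  if (!is.null(out_file)) {
    utils::write.csv(observed, out_file, row.names = FALSE, quote = FALSE)
  }
  list(observed = observed, predictions = preds, tracer = tracer,
       truth_route = plan$route)
}
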