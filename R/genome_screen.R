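#' Parse a BLAST tabular (12-column) hit file
#'
#' Reads translated-homology hits in the classic 12-column tabular dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). Reversed subject coordinates (sstart > send) are
#' normalized to ascending order with strand set to `-`.
#'
#' @param path Path to a tab-separated hit file (no header).
#' @return `data.frame` with columns `query_gene`, `subject_id`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`, `e_value`,
#'   `bit_score`, `strand`. Empty file gives zero rows.
#' @export
parse_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_hits())
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, integer(1)) != 12)
  if (length(bad)) {
    stop("malformed hit line ", bad[1], " in '", path, "': expected 12 ",
         "tab-separated columns, found ", length(rows[[bad[1]]]))
  }
  m <- do.call(rbind, rows)
  df <- data.frame(
    query_gene = m[, 1],
    subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    align_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]),
    gap_opens = as.integer(m[, 6]),
    query_start = as.integer(m[, 7]),
    query_end = as.integer(m[, 8]),
    subject_start = as.integer(m[, 9]),
    subject_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]),
    bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$percent_identity) || anyNA(df$subject_start) ||
      anyNA(df$subject_end) || anyNA(df$e_value)) {
    bad <- which(is.na(df$percent_identity) | is.na(df$subject_start) |
                 is.na(df$subject_end) | is.na(df$e_value))[1]
    stop("malformed hit line ", bad, " in '", path, "': non-numeric field")
  }
  rev_idx <- df$subject_start > df$subject_end
  df$strand <- ifelse(rev_idx, "-", "+")
  tmp <- df$subject_start[rev_idx]
  df$subject_start[rev_idx] <- df$subject_end[rev_idx]
  df$subject_end[rev_idx] <- tmp
  df
}

empty_hits <- function() {
  data.frame(query_gene = character(0), subject_id = character(0),
             percent_identity = numeric(0), align_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             query_start = integer(0), query_end = integer(0),
             subject_start = integer(0), subject_end = integer(0),
             e_value = numeric(0), bit_score = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Write hits in the 12-column BLAST tabular dialect
#'
#' Inverse of [parse_hits()]: minus-strand hits are written with reversed
#' subject coordinates.
#'
#' @param hits Hit `data.frame` (as from [parse_hits()] or
#'   [six_frame_search()]).
#' @param path Output file.
#' @export
write_hits_tabular <- function(hits, path) {
  ss <- hits$subject_start
  se <- hits$subject_end
  rev_idx <- hits$strand == "-"
  tmp <- ss[rev_idx]
  ss[rev_idx] <- se[rev_idx]
  se[rev_idx] <- tmp
  m <- cbind(hits$query_gene, hits$subject_id,
             format(hits$percent_identity, trim = TRUE),
             hits$align_length, hits$mismatches, hits$gap_opens,
             hits$query_start, hits$query_end, ss, se,
             format(hits$e_value, trim = TRUE),
             format(hits$bit_score, trim = TRUE))
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Filter hits on identity and e-value
#'
#' Keeps hits with `percent_identity >= min_identity` and
#' `e_value <= max_evalue`; both thresholds are inclusive. Defaults are the
#' screen's canonical parameters (25% translated identity, e-value 1e-4).
#' An optional query-coverage filter (off by default) drops hits whose
#' alignment covers less than `min_query_coverage` of the query length.
#'
#' @param hits Hit `data.frame`.
#' @param min_identity Minimum percent identity (inclusive), default 25.
#' @param max_evalue Maximum e-value (inclusive), default 1e-4.
#' @param min_query_coverage Optional fraction in `(0, 1]`; requires
#'   `query_lengths`.
#' @param query_lengths Named vector of query lengths (residues), needed only
#'   with `min_query_coverage`.
#' @return Filtered `data.frame`.
#' @export
filter_hits <- function(hits, min_identity = 25.0, max_evalue = 1e-4,
                        min_query_coverage = NULL, query_lengths = NULL) {
  keep <- hits$percent_identity >= min_identity & hits$e_value <= max_evalue
  if (!is.null(min_query_coverage)) {
    if (is.null(query_lengths)) {
      stop("min_query_coverage requires query_lengths")
    }
    qlen <- query_lengths[hits$query_gene]
    keep <- keep & (hits$align_length / qlen >= min_query_coverage)
  }
  hits[keep, , drop = FALSE]
}

#' Chain hits into co-occurrence clusters
#'
#' Single-linkage chaining of hit intervals per subject sequence: two hits
#' join one cluster when the gap between their intervals
#' (`max(0, next_start - prev_end - 1)`; overlapping intervals have gap 0) is
#' at most `window_bp`, directly or through intermediate hits. Clustering is
#' strand-agnostic and invariant to input order. With
#' `anchor = "start"` the start-to-start distance is used instead of the
#' inter-interval gap.
#'
#' @param hits Hit `data.frame` (normally already filtered).
#' @param window_bp Maximum chaining distance in bp (default 20000).
#' @param anchor `"gap"` (default; inter-interval gap) or `"start"`
#'   (start-to-start distance).
#' @return List of clusters; each is a list with `subject_id`, `start`,
#'   `end`, `genes` (distinct query genes) and `hits` (the member rows).
#' @export
cluster_cooccurrence <- function(hits, window_bp = 20000,
                                 anchor = c("gap", "start")) {
  anchor <- match.arg(anchor)
  clusters <- list()
  for (sid in unique(hits$subject_id)) {
    sub <- hits[hits$subject_id == sid, , drop = FALSE]
    sub <- sub[order(sub$subject_start, sub$subject_end), , drop = FALSE]
    cl_start <- 1
    run_end <- sub$subject_end[1]
    flush <- function(from, to) {
      rows <- sub[from:to, , drop = FALSE]
      clusters[[length(clusters) + 1]] <<- list(
        subject_id = sid,
        start = min(rows$subject_start),
        end = max(rows$subject_end),
        genes = sort(unique(rows$query_gene)),
        hits = rows
      )
    }
    if (nrow(sub) >= 2) {
      for (i in 2:nrow(sub)) {
        dist <- if (anchor == "gap") {
          max(0, sub$subject_start[i] - run_end - 1)
        } else {
          sub$subject_start[i] - sub$subject_start[cl_start]
        }
        if (dist > window_bp) {
          flush(cl_start, i - 1)
          cl_start <- i
          run_end <- sub$subject_end[i]
        } else {
          run_end <- max(run_end, sub$subject_end[i])
        }
      }
    }
    flush(cl_start, nrow(sub))
  }
  clusters
}

#' Export clusters as a BED-like table
#'
#' @param clusters List from [cluster_cooccurrence()].
#' @return `data.frame` with columns `subject_id`, `start`, `end`,
#'   `n_genes`, `genes` (semicolon-separated).
#' @export
clusters_as_table <- function(clusters) {
  if (length(clusters) == 0) {
    return(data.frame(subject_id = character(0), start = integer(0),
                      end = integer(0), n_genes = integer(0),
                      genes = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    subject_id = vapply(clusters, `[[`, character(1), "subject_id"),
    start = vapply(clusters, `[[`, numeric(1), "start"),
    end = vapply(clusters, `[[`, numeric(1), "end"),
    n_genes = vapply(clusters, function(cl) length(cl$genes), integer(1)),
    genes = vapply(clusters, function(cl) paste(cl$genes, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE
  )
}

#' Define a complex presence rule
#'
#' @param complex_name Name of the complex.
#' @param gene_ids Gene ids making up the complex.
#' @param min_detected Minimum number of distinct genes that must be detected.
#' @param requires_cooccurrence Must the genes co-occur in one cluster
#'   (default TRUE)?
#' @param window_bp Co-occurrence window (default 20000).
#' @return A `complex_rule` object.
#' @export
complex_rule <- function(complex_name, gene_ids, min_detected,
                         requires_cooccurrence = TRUE, window_bp = 20000) {
  if (min_detected < 1 || min_detected > length(gene_ids)) {
    stop("min_detected must be between 1 and the number of genes")
  }
  structure(list(complex_name = complex_name, gene_ids = gene_ids,
                 min_detected = as.integer(min_detected),
                 requires_cooccurrence = requires_cooccurrence,
                 window_bp = window_bp),
            class = "complex_rule")
}

#' Evaluate a complex presence rule against clusters
#'
#' A complex with `requires_cooccurrence = TRUE` is present when some single
#' cluster contains hits to at least `min_detected` distinct genes of the
#' rule; multiple hits to the same gene count once. Without the
#' co-occurrence requirement, distinct genes are counted across all clusters
#' (genome-wide).
#'
#' @param clusters List from [cluster_cooccurrence()] (built from this
#'   complex's hits).
#' @param rule A [complex_rule()].
#' @return List with `present`, `best_count` and `best_cluster` (NULL when no
#'   cluster hits the rule's genes).
#' @export
evaluate_complex <- function(clusters, rule) {
  counts <- vapply(clusters, function(cl) {
    length(intersect(cl$genes, rule$gene_ids))
  }, integer(1))
  if (!rule$requires_cooccurrence) {
    all_genes <- unique(unlist(lapply(clusters, `[[`, "genes")))
    n <- length(intersect(all_genes, rule$gene_ids))
    return(list(present = n >= rule$min_detected, best_count = n,
                best_cluster = NULL))
  }
  if (length(counts) == 0 || max(counts) == 0) {
    return(list(present = FALSE, best_count = 0L, best_cluster = NULL))
  }
  best <- which.max(counts)
  list(present = counts[best] >= rule$min_detected,
       best_count = counts[best],
       best_cluster = clusters[[best]])
}

#' Load a pathway screening ruleset
#'
#' Reads a YAML ruleset (complex rules, single genes, route logic and the
#' default thresholds). The package ships the reductive glycine pathway
#' ruleset: GCS 3-of-4, GR 5-of-7, four alternative FDH complexes, the
#' formate-THF ligase and methenyl-THF cyclohydrolase as required singles,
#' route A = GR + (PTA | ACK) and route B = SHMT + SDA.
#'
#' @param path Ruleset YAML; defaults to the shipped rGly ruleset.
#' @return An `rgly_ruleset` object.
#' @export
load_ruleset <- function(path = system.file("extdata", "rgly_ruleset.yaml",
                                            package = "rglypath")) {
  raw <- yaml::read_yaml(path)
  window <- as.numeric(raw$window_bp %||% 20000)
  complexes <- list()
  for (nm in names(raw$complexes)) {
    cc <- raw$complexes[[nm]]
    complexes[[nm]] <- complex_rule(
      nm, as.character(unlist(cc$genes)), cc$min_detected,
      isTRUE(cc$requires_cooccurrence %||% TRUE), window
    )
  }
  singles <- vapply(raw$singles, as.character, character(1))
  pw <- raw$pathway
  ruleset <- structure(list(
    window_bp = window,
    min_identity = as.numeric(raw$min_identity %||% 25.0),
    max_evalue = as.numeric(raw$max_evalue %||% 1e-4),
    complexes = complexes,
    singles = singles,
    required_singles = as.character(unlist(pw$required_singles)),
    fdh_complexes = as.character(unlist(pw$fdh_complexes)),
    gcs = pw$gcs,
    route_A = list(complex = pw$route_A$complex,
                   any_of_singles = as.character(unlist(pw$route_A$any_of_singles))),
    route_B = as.character(unlist(pw$route_B$singles))
  ), class = "rgly_ruleset")
  bad <- setdiff(c(ruleset$fdh_complexes, ruleset$gcs, ruleset$route_A$complex),
                 names(complexes))
  if (length(bad)) stop("ruleset references unknown complex(es): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(c(ruleset$required_singles, ruleset$route_A$any_of_singles,
                   ruleset$route_B), names(singles))
  if (length(bad)) stop("ruleset references unknown single gene role(s): ",
                        paste(bad, collapse = ", "))
  ruleset
}

#' Apply the two-route pathway logic to per-genome presence calls
#'
#' @param complex_present Named logical vector over the ruleset's complexes.
#' @param single_present Named logical vector over the ruleset's single-gene
#'   roles.
#' @param ruleset An [load_ruleset()] ruleset.
#' @param mode `"require_fdh"` (default) or `"fdh_optional"` (the FDH clause
#'   is skipped).
#' @return List with `fdh_present`, `core_present`, `route_A`, `route_B`,
#'   `both` and `mode`. `route_A`/`route_B` are full pathway calls through
#'   that route (core requirements included).
#' @export
evaluate_pathway <- function(complex_present, single_present, ruleset,
                             mode = c("require_fdh", "fdh_optional")) {
  mode <- match.arg(mode)
  fdh <- any(complex_present[ruleset$fdh_complexes])
  core <- (fdh || mode == "fdh_optional") &&
    complex_present[[ruleset$gcs]] &&
    all(single_present[ruleset$required_singles])
  route_a <- core && complex_present[[ruleset$route_A$complex]] &&
    any(single_present[ruleset$route_A$any_of_singles])
  route_b <- core && all(single_present[ruleset$route_B])
  list(fdh_present = fdh, core_present = core,
       route_A = route_a, route_B = route_b,
       both = route_a && route_b, mode = mode)
}

#' Screen genomes for the pathway from translated-homology hit tables
#'
#' Runs the full rule pipeline per genome: inclusive identity/e-value
#' filtering, per-complex 20-kb co-occurrence chaining (each complex's
#' clusters are built from its own hits, per subject sequence), per-complex
#' minimum-distinct-gene rules, genome-wide single-gene detection, and the
#' two-route pathway logic with or without the FDH requirement.
#'
#' @param hits Hit `data.frame` from [parse_hits()] or [six_frame_search()],
#'   or a path to a 12-column tabular hit file.
#' @param ruleset An [load_ruleset()] ruleset (default: shipped rGly rules).
#' @param mode `"require_fdh"` (default) or `"fdh_optional"`.
#' @param genome_map Optional `data.frame` with columns `subject_id`,
#'   `genome` aggregating subject sequences (contigs) into genomes; absent a
#'   mapping, each subject id is its own genome.
#' @param min_identity,max_evalue,window_bp Threshold overrides; default to
#'   the ruleset's values.
#' @param anchor Passed to [cluster_cooccurrence()].
#' @return `data.frame`, one row per genome: per-complex presence and
#'   distinct-gene counts, single-gene presence, `fdh_present`,
#'   `core_present`, `route_A`, `route_B`, `both_routes` and `mode`.
#'   Genomes named in `genome_map` but without hits get all-absent rows.
#' @export
screen <- function(hits, ruleset = load_ruleset(),
                   mode = c("require_fdh", "fdh_optional"),
                   genome_map = NULL,
                   min_identity = ruleset$min_identity,
                   max_evalue = ruleset$max_evalue,
                   window_bp = ruleset$window_bp,
                   anchor = "gap") {
  mode <- match.arg(mode)
  if (is.character(hits) && length(hits) == 1) hits <- parse_hits(hits)
  hits <- filter_hits(hits, min_identity = min_identity,
                      max_evalue = max_evalue)

  if (is.null(genome_map)) {
    hits$genome <- hits$subject_id
    genomes <- unique(hits$genome)
  } else {
    stopifnot(all(c("subject_id", "genome") %in% names(genome_map)))
    hits$genome <- genome_map$genome[match(hits$subject_id,
                                           genome_map$subject_id)]
    if (anyNA(hits$genome)) {
      stop("subject id(s) missing from genome_map: ",
           paste(unique(hits$subject_id[is.na(hits$genome)]), collapse = ", "))
    }
    genomes <- unique(genome_map$genome)
  }

  rows <- lapply(genomes, function(g) {
    gh <- hits[hits$genome == g, , drop = FALSE]
    complex_present <- logical(0)
    complex_count <- integer(0)
    for (nm in names(ruleset$complexes)) {
      rule <- ruleset$complexes[[nm]]
      sub <- gh[gh$query_gene %in% rule$gene_ids, , drop = FALSE]
      ev <- if (nrow(sub) == 0) {
        list(present = FALSE, best_count = 0L)
      } else {
        evaluate_complex(cluster_cooccurrence(sub, window_bp, anchor), rule)
      }
      complex_present[nm] <- ev$present
      complex_count[nm] <- ev$best_count
    }
    single_present <- vapply(names(ruleset$singles), function(role) {
      ruleset$singles[[role]] %in% gh$query_gene
    }, logical(1))
    pw <- evaluate_pathway(complex_present, single_present, ruleset, mode)

    row <- c(list(genome = g),
             as.list(stats::setNames(complex_present,
                                     paste0(names(complex_present), "_present"))),
             as.list(stats::setNames(complex_count,
                                     paste0(names(complex_count), "_count"))),
             as.list(stats::setNames(single_present,
                                     paste0(names(single_present), "_present"))),
             list(fdh_present = pw$fdh_present, core_present = pw$core_present,
                  route_A = pw$route_A, route_B = pw$route_B,
                  both_routes = pw$both, mode = mode))
    as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
  })
  if (length(rows) == 0) {
    # empty hit table: produce the empty frame with the right columns
    cn <- c("genome",
            paste0(names(ruleset$complexes), "_present"),
            paste0(names(ruleset$complexes), "_count"),
            paste0(names(ruleset$singles), "_present"),
            "fdh_present", "core_present", "route_A", "route_B",
            "both_routes", "mode")
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cn)), cn),
                        check.names = FALSE)
    df$genome <- character(0)
    df$mode <- character(0)
    return(df)
  }
  do.call(rbind, rows)
}
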