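ruleset <- load_ruleset()

hit_line <- function(q = "g1", s = "chr1", pid = 90, len = 100, ss = 1000,
                     se = 1300, ev = 1e-20) {
  paste(q, s, pid, len, 5, 0, 1, len, ss, se, ev, 200, sep = "\t")
}

make_hit <- function(q = "g1", s = "chr1", start = 1, end = 300, pid = 90,
                     ev = 1e-20) {
  data.frame(query_gene = q, subject_id = s, percent_identity = pid,
             align_length = 100L, mismatches = 5L, gap_opens = 0L,
             query_start = 1L, query_end = 100L,
             subject_start = start, subject_end = end, e_value = ev,
             bit_score = 200, strand = "+", stringsAsFactors = FALSE)
}

test_that("tabular hits parse, normalize reversed coordinates, and reject junk", {
  path <- tempfile()
  writeLines(c(hit_line(ss = 1000, se = 1300),
               hit_line(q = "g2", ss = 5300, se = 5000)), path)
  hits <- parse_hits(path)
  expect_identical(hits$strand, c("+", "-"))
  expect_equal(hits$subject_start, c(1000, 5000))
  expect_equal(hits$subject_end, c(1300, 5300))

  empty <- tempfile(); file.create(empty)
  expect_identical(nrow(parse_hits(empty)), 0L)

  bad <- tempfile()
  writeLines(c(hit_line(), "only\televen\tcolumns\t1\t2\t3\t4\t5\t6\t7\t8"), bad)
  expect_error(parse_hits(bad), "line 2")

  # round-trip through the writer preserves the records
  out <- tempfile()
  write_hits_tabular(hits, out)
  again <- parse_hits(out)
  expect_equal(again$subject_start, hits$subject_start)
  expect_identical(again$strand, hits$strand)
})

test_that("identity and e-value thresholds are inclusive", {
  hits <- rbind(make_hit(q = "keep_boundary", pid = 25.0, ev = 1e-4),
                make_hit(q = "keep_clear", pid = 80, ev = 1e-30),
                make_hit(q = "drop_identity", pid = 24.9, ev = 1e-30),
                make_hit(q = "drop_evalue", pid = 80, ev = 1e-3))
  kept <- filter_hits(hits)$query_gene
  expect_setequal(kept, c("keep_boundary", "keep_clear"))
})

test_that("co-occurrence chaining respects the window and single linkage", {
  # gap of 5,000: one cluster; 25,000: two
  h <- rbind(make_hit("a", start = 1, end = 1000),
             make_hit("b", start = 6001, end = 7000))
  expect_length(cluster_cooccurrence(h, 20000), 1)
  h2 <- rbind(make_hit("a", start = 1, end = 1000),
              make_hit("b", start = 26001, end = 27000))
  expect_length(cluster_cooccurrence(h2, 20000), 2)

  # chained: consecutive gaps of 15,000 connect all three
  h3 <- rbind(make_hit("a", start = 1, end = 1000),
              make_hit("b", start = 16001, end = 17000),
              make_hit("c", start = 32001, end = 33000))
  cl <- cluster_cooccurrence(h3, 20000)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$genes, c("a", "b", "c"))

  # exact boundary: gap of 20,000 merges, 20,001 splits
  h4 <- rbind(make_hit("a", start = 1, end = 1000),
              make_hit("b", start = 21001, end = 22000))  # gap 20,000
  expect_length(cluster_cooccurrence(h4, 20000), 1)
  h5 <- rbind(make_hit("a", start = 1, end = 1000),
              make_hit("b", start = 21002, end = 22000))  # gap 20,001
  expect_length(cluster_cooccurrence(h5, 20000), 2)
})

test_that("chaining matches the pairwise-closure oracle and is order-invariant", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    starts <- sort(sample.int(200000L, n))
    hits <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_hit(paste0("g", i),
               s = sample(c("c1", "c2"), 1),
               start = starts[i], end = starts[i] + sample.int(5000L, 1))
    }))
    window <- sample(c(5000L, 20000L), 1)
    cl <- cluster_cooccurrence(hits, window)
    # same partition as the brute-force connected-components oracle
    want <- oracle_cluster_membership(hits, window)
    got <- integer(nrow(hits))
    for (k in seq_along(cl)) {
      idx <- match(paste(cl[[k]]$hits$query_gene, cl[[k]]$hits$subject_start),
                   paste(hits$query_gene, hits$subject_start))
      got[idx] <- k
    }
    expect_identical(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(got, want, function(v) length(unique(v)) == 1)))

    # permuting the input rows yields the same cluster table
    perm <- sample(nrow(hits))
    tab1 <- clusters_as_table(cl)
    tab2 <- clusters_as_table(cluster_cooccurrence(hits[perm, ], window))
    ord <- function(t) t[order(t$subject_id, t$start), , drop = FALSE]
    expect_equal(ord(tab2), ord(tab1), ignore_attr = TRUE)

    # no two clusters on one subject lie within the window of each other
    tab <- ord(tab1)
    for (s in unique(tab$subject_id)) {
      st <- tab[tab$subject_id == s, ]
      if (nrow(st) > 1) {
        gaps <- st$start[-1] - st$end[-nrow(st)] - 1
        expect_true(all(gaps > window))
      }
    }
  }
})

test_that("complex rules count distinct genes within one cluster", {
  gcs <- ruleset$complexes$GCS
  g <- gcs$gene_ids
  hits3 <- do.call(rbind, lapply(1:3, function(i)
    make_hit(g[i], start = i * 1000, end = i * 1000 + 500)))
  ev <- evaluate_complex(cluster_cooccurrence(hits3, 20000), gcs)
  expect_true(ev$present)
  expect_identical(ev$best_count, 3L)

  # repeated hits to one gene still count once
  hits_dup <- rbind(hits3[1, ], hits3[1, ], hits3[1, ])
  ev_dup <- evaluate_complex(cluster_cooccurrence(hits_dup, 20000), gcs)
  expect_false(ev_dup$present)
  expect_identical(ev_dup$best_count, 1L)

  gr <- ruleset$complexes$GR
  hits4 <- do.call(rbind, lapply(1:4, function(i)
    make_hit(gr$gene_ids[i], start = i * 1000, end = i * 1000 + 500)))
  ev4 <- evaluate_complex(cluster_cooccurrence(hits4, 20000), gr)
  expect_false(ev4$present)  # 4 of 7 < min 5
  expect_identical(ev4$best_count, 4L)

  expect_false(evaluate_complex(list(), gr)$present)
  expect_identical(evaluate_complex(list(), gr)$best_count, 0L)
})

test_that("adding hits never flips a complex from present to absent", {
  set.seed(23)
  gcs <- ruleset$complexes$GCS
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    hits <- do.call(rbind, lapply(seq_len(n), function(i)
      make_hit(sample(gcs$gene_ids, 1), start = sample.int(60000L, 1))))
    hits$subject_end <- hits$subject_start + 500L
    before <- evaluate_complex(cluster_cooccurrence(hits, 20000), gcs)$present
    extra <- make_hit(sample(gcs$gene_ids, 1), start = sample.int(60000L, 1))
    extra$subject_end <- extra$subject_start + 500L
    after <- evaluate_complex(cluster_cooccurrence(rbind(hits, extra), 20000),
                              gcs)$present
    expect_true(!before || after)
  }
})

test_that("two-route pathway logic follows the presence rules", {
  cx <- setNames(rep(FALSE, length(ruleset$complexes)),
                 names(ruleset$complexes))
  sg <- setNames(rep(FALSE, length(ruleset$singles)), names(ruleset$singles))
  cx[c("FDH_1.17.2.3", "GCS", "GR")] <- TRUE
  sg[c("FTL", "MTCD", "ACK")] <- TRUE
  pw <- evaluate_pathway(cx, sg, ruleset)
  expect_true(pw$route_A); expect_false(pw$route_B); expect_false(pw$both)

  sg[c("SHMT", "SDA")] <- TRUE
  pw2 <- evaluate_pathway(cx, sg, ruleset)
  expect_true(pw2$route_A && pw2$route_B && pw2$both)

  # FDH missing: absent in require_fdh mode, rescued by fdh_optional
  cx["FDH_1.17.2.3"] <- FALSE
  pw3 <- evaluate_pathway(cx, sg, ruleset, mode = "require_fdh")
  expect_false(pw3$route_A || pw3$route_B)
  pw4 <- evaluate_pathway(cx, sg, ruleset, mode = "fdh_optional")
  expect_true(pw4$route_A && pw4$route_B)
})

test_that("six-frame search finds planted ORFs with exact coordinates", {
  set.seed(5)
  prot <- random_protein(80)
  orf <- back_translate(prot)
  flank1 <- paste(sample(c("A", "C", "G", "T"), 211, replace = TRUE),
                  collapse = "")
  flank2 <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                  collapse = "")
  genome <- paste0(flank1, orf, flank2)
  q <- Biostrings::AAStringSet(setNames(prot, "q1"))

  hits <- six_frame_search(Biostrings::DNAStringSet(setNames(genome, "chr")), q)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$percent_identity, 100)
  expect_identical(best$strand, "+")
  expect_equal(best$subject_start, 212)
  expect_equal(best$subject_end, 211 + 3 * nchar(prot))

  # reverse complement: same identity, minus strand, same coordinates
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome)))
  hits_rc <- six_frame_search(Biostrings::DNAStringSet(setNames(rc, "chr")), q)
  best_rc <- hits_rc[which.max(hits_rc$score), ]
  expect_equal(best_rc$percent_identity, 100)
  expect_identical(best_rc$strand, "-")
  expect_equal(best_rc$subject_start, nchar(genome) - best$subject_end + 1)
  expect_equal(best_rc$subject_end, nchar(genome) - best$subject_start + 1)
  expect_equal(best_rc$score, best$score)

  # one mismatched residue in the middle of the query
  prot_mm <- prot
  substr(prot_mm, 40, 40) <- if (substr(prot, 40, 40) == "A") "W" else "A"
  hits_mm <- six_frame_search(
    Biostrings::DNAStringSet(setNames(genome, "chr")),
    Biostrings::AAStringSet(setNames(prot_mm, "q1")))
  best_mm <- hits_mm[which.max(hits_mm$score), ]
  expect_equal(best_mm$percent_identity, round(100 * 79 / 80, 2))

  expect_error(six_frame_search(Biostrings::DNAStringSet(), q), "empty genome")
})

test_that("six-frame best score matches the quadratic DP oracle", {
  set.seed(9)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  for (rep in 1:3) {
    prot <- random_protein(40)
    orf <- back_translate(prot)
    genome <- paste0(
      paste(sample(c("A", "C", "G", "T"), sample(100:200, 1), replace = TRUE),
            collapse = ""),
      orf,
      paste(sample(c("A", "C", "G", "T"), sample(100:200, 1), replace = TRUE),
            collapse = ""))
    query <- random_protein(40)
    if (rep == 1) query <- prot  # include a true positive
    hits <- six_frame_search(
      Biostrings::DNAStringSet(setNames(genome, "chr")),
      Biostrings::AAStringSet(setNames(query, "q")), min_score = 1)
    got <- if (nrow(hits)) max(hits$score) else 0
    want <- max(vapply(oracle_six_frames(genome), function(fr)
      oracle_sw_score(query, fr, BLOSUM62), numeric(1)))
    expect_equal(got, want)
  }
})

test_that("screen recovers the planted truth on a small genome set", {
  plan <- genome_plan(n_genomes = 12, seed = 31, emit_sequences = FALSE)
  g <- make_genomes(plan)
  res <- screen(g$hits, genome_map = g$genome_map)
  merged <- merge(g$truth, res, by = "genome", suffixes = c(".truth", ""))
  expect_identical(nrow(merged), 12L)
  expect_identical(merged$route_A, merged$route_A.truth)
  expect_identical(merged$route_B, merged$route_B.truth)
  expect_identical(merged$both_routes, merged$both_routes.truth)

  # empty hit table: a valid, empty result frame
  empty <- screen(g$hits[0, ], genome_map = NULL)
  expect_s3_class(empty, "data.frame")
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("route_A", "route_B", "both_routes") %in% names(empty)))
})
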