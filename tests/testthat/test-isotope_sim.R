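model <- load_pathway_model()
ideal <- tracer_config(list(formate = 1, CO2 = 0))
realistic <- tracer_config()  # 0.99 formate, natural-abundance CO2

test_that("an ideal formate tracer gives the canonical route signatures", {
  d <- propagate("rGly-GR-PTA", ideal, model)
  # glycine: carboxyl from CO2 (unlabelled), alpha from formate (labelled)
  expect_equal(unname(d$glycine$prob[["01"]]), 1)
  expect_equal(unname(mid_of(d$glycine)), c(0, 1, 0))
  expect_equal(unname(mid_of(d$pyruvate)), c(0, 1, 0, 0))   # GR route M+1
  expect_equal(unname(mid_of(d$acetylCoA)), c(0, 1, 0))

  d_ser <- propagate("rGly-serine", ideal, model)
  expect_equal(unname(mid_of(d_ser$serine)), c(0, 0, 1, 0))  # M+2
  expect_equal(unname(mid_of(d_ser$pyruvate)), c(0, 0, 1, 0))
})

test_that("an unlabelled tracer leaves every compound at M+0", {
  zero <- tracer_config(list(formate = 0, CO2 = 0))
  d <- propagate("GR", zero, model)
  for (cid in names(d)) {
    mid <- mid_of(d[[cid]])
    expect_equal(unname(mid[1]), 1, info = cid)
  }
})

test_that("propagated MIDs equal the exhaustive pattern-enumeration oracle", {
  for (route in c("GR", "serine")) {
    ids <- model$networks[[route]]
    d <- propagate(route, realistic, model)
    for (cid in names(d)) {
      got <- unname(mid_of(d[[cid]]))
      want <- oracle_mid(model, ids, realistic, cid)
      expect_lt(max(abs(got - want)), 1e-12)
      expect_equal(sum(got), 1, tolerance = 1e-9)
    }
  }
})

test_that("glycine M+1 under the 99% tracer matches the closed form", {
  d <- propagate("rGly-GR-PTA", realistic, model)
  mid <- mid_of(d$glycine)
  e1 <- 0.0107; e2 <- 0.99
  expect_equal(unname(mid[["M1"]]), e1 * (1 - e2) + e2 * (1 - e1),
               tolerance = 1e-12)
})

test_that("glycine labelling is monotone in formate enrichment", {
  expected_labels <- vapply(seq(0, 1, by = 0.1), function(p) {
    tr <- tracer_config(list(formate = p, CO2 = 0.0107))
    mid <- mid_of(propagate("rGly-GR-PTA", tr, model)$glycine)
    sum((seq_along(mid) - 1) * mid)
  }, numeric(1))
  expect_true(all(diff(expected_labels) >= -1e-12))
})

test_that("mid_of collapses positional patterns by label count", {
  # uniform over the all-unlabelled and all-labelled 2-carbon patterns
  dist <- structure(list(compound_id = "glycine", n_carbons = 2L,
                         prob = c("00" = 0.5, "10" = 0, "01" = 0, "11" = 0.5)),
                    class = "positional_dist")
  expect_equal(unname(mid_of(dist)), c(0.5, 0, 0.5))
})

test_that("degenerate networks are rejected with clear errors", {
  # GCS alone: methylene-THF has neither tracer spec nor producer
  expect_error(propagate(c("GCS"), ideal, model),
               "no tracer specification and no producing reaction")
  cyc <- load_pathway_model(write_cyclic_model())
  expect_error(propagate("loop", tracer_config(list(Z = 1)), cyc),
               "cyclic")
})

test_that("amino-acid predictions shift by one labelled carbon per route", {
  gr <- predict_amino_acid_mids("GR", ideal, model)
  ser <- predict_amino_acid_mids("serine", ideal, model)
  point <- function(mid) which(as.numeric(mid) == 1) - 1
  # glycine/serine identical between routes; pyruvate family shifts
  expect_equal(point(gr$glycine), 1); expect_equal(point(ser$glycine), 1)
  expect_equal(point(gr$serine), 2);  expect_equal(point(ser$serine), 2)
  expect_equal(point(gr$alanine), 1); expect_equal(point(ser$alanine), 2)
  expect_equal(point(gr$PEP), 1);     expect_equal(point(ser$PEP), 2)
  expect_equal(point(gr$threonine), 1)
  expect_equal(point(gr$valine), 2)   # two pyruvates, one methyl label each
  expect_equal(point(gr$leucine), 3)  # + the acetyl-CoA methyl
  expect_equal(point(gr$proline), 2)
  expect_error(predict_amino_acid_mids("GR", ideal, model,
                                       metabolites = "caffeine"),
               "not produced")
})

test_that("route classification recovers exact predictions and flags ties", {
  gr_pred <- predict_amino_acid_mids("GR", realistic, model)
  ser_pred <- predict_amino_acid_mids("serine", realistic, model)

  call_gr <- classify_route(gr_pred, realistic, model)
  expect_identical(call_gr$route, "GR")
  expect_equal(call_gr$score_GR, 0)
  expect_gt(call_gr$score_serine, call_gr$score_GR)

  call_ser <- classify_route(ser_pred, realistic, model)
  expect_identical(call_ser$route, "serine")

  # permutation invariance in the metabolite set
  shuffled <- ser_pred[rev(names(ser_pred))]
  call_shuf <- classify_route(shuffled, realistic, model)
  expect_identical(call_shuf$route, call_ser$route)
  expect_equal(call_shuf$score_GR, call_ser$score_GR)

  # the midpoint of the two predictions is ambiguous
  mixed <- Map(function(a, b) (a + b) / 2, gr_pred, ser_pred)
  expect_identical(classify_route(mixed, realistic, model)$route, "ambiguous")

  # glycine and serine alone cannot discriminate the routes
  expect_error(classify_route(gr_pred[c("glycine", "serine")],
                              realistic, model),
               "no discriminating metabolite")
})

test_that("MID CSVs round-trip through the long dialect", {
  mids <- predict_amino_acid_mids("GR", realistic, model)
  path <- tempfile(fileext = ".csv")
  write_mid_csv(mids, path)
  df <- read_mid_csv(path)
  call <- classify_route(df, realistic, model)
  expect_identical(call$route, "GR")
})
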