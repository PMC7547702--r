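#' Tracer configuration for 13C label propagation
#'
#' Describes per-carbon 13C enrichment of the labelling substrates. The
#' default mirrors the formate-tracer experiment: 99 atom-% 13C formate in an
#' excess of CO2 at natural 13C abundance.
#'
#' @param enrichments Named list mapping substrate compound ids to the 13C
#'   fraction per carbon position (scalar, recycled, or a per-position
#'   vector). All fractions must lie in `[0, 1]`.
#' @param natural_abundance_p13 Background 13C fraction (default 0.0107),
#'   used by callers that need the natural-abundance rate.
#' @return An object of class `tracer_config`.
#' @export
#' @examples
#' tracer_config()                              # 0.99 formate / 0.0107 CO2
#' tracer_config(list(formate = 1, CO2 = 0))    # idealized tracer
tracer_config <- function(enrichments = list(formate = 0.99, CO2 = 0.0107),
                          natural_abundance_p13 = 0.0107) {
  vals <- unlist(enrichments)
  if (any(vals < 0 | vals > 1)) stop("tracer enrichments must be in [0, 1]")
  if (natural_abundance_p13 < 0 || natural_abundance_p13 >= 1) {
    stop("natural_abundance_p13 must be in [0, 1)")
  }
  structure(list(enrichments = enrichments,
                 natural_abundance_p13 = natural_abundance_p13),
            class = "tracer_config")
}

# joint positional distribution of independent Bernoulli-labelled carbons;
# patterns are indexed 0..2^n-1 with carbon i on bit i-1.
bernoulli_joint <- function(enrich, n) {
  e <- rep_len(as.numeric(enrich), n)
  p <- 1
  for (i in seq_len(n)) {
    p <- as.vector(outer(p, c(1 - e[i], e[i])))
  }
  p
}

pattern_names <- function(n) {
  if (n == 0) return("")
  # carbon 1 is the leftmost character
  vapply(0:(2^n - 1), function(k) {
    paste(as.integer(intToBits(k)[seq_len(n)]), collapse = "")
  }, character(1))
}

# marginal joint distribution over a subset of positions (in the given order)
marginal_joint <- function(p, n, positions) {
  m <- length(positions)
  out <- numeric(2^m)
  for (k in 0:(2^n - 1)) {
    bits <- bitwAnd(bitwShiftR(k, positions - 1L), 1L)
    idx <- sum(bits * 2^(seq_len(m) - 1)) + 1
    out[idx] <- out[idx] + p[k + 1]
  }
  out
}

#' Propagate positional 13C labels through a pathway variant
#'
#' Computes, for every compound produced in the variant's reaction network,
#' the joint distribution over binary carbon-labelling patterns implied by the
#' atom transitions. Tracer substrates are labelled independently per position
#' with their configured enrichment; every product carbon inherits the
#' distribution of its mapped source carbon; condensation products carry the
#' product of their (assumed independent, well-mixed) substrate pools.
#' Released CO2 does not re-enter the labelled pool: compounds named in the
#' tracer are treated as fixed source pools even when the network also
#' produces them.
#'
#' @param variant An `rgly_variant`, a variant/network name in `model`
#'   (variants are looked up first, then label networks), or a character
#'   vector of reaction ids.
#' @param tracer A [tracer_config()].
#' @param model An `rgly_model`.
#' @return Named list of `positional_dist` objects, one per non-source
#'   compound: each has `compound_id`, `n_carbons` and `prob` (vector over
#'   the `2^n` labelling patterns, named by binary pattern with carbon 1
#'   leftmost).
#' @export
#' @examples
#' model <- load_pathway_model()
#' d <- propagate("rGly-GR-PTA", tracer_config(list(formate = 1, CO2 = 0)), model)
#' d$glycine$prob  # all mass on pattern "01" (C2 labelled)
propagate <- function(variant, tracer, model) {
  reaction_ids <-
    if (inherits(variant, "rgly_variant")) {
      resolve_variant(variant, model)$steps$reaction
    } else if (is.character(variant) && length(variant) == 1 &&
               variant %in% names(model$variants)) {
      model$variants[[variant]]$steps$reaction
    } else if (is.character(variant) && length(variant) == 1 &&
               variant %in% names(model$networks)) {
      model$networks[[variant]]
    } else if (is.character(variant)) {
      variant
    } else {
      stop("cannot interpret 'variant'")
    }
  missing <- setdiff(reaction_ids, names(model$reactions))
  if (length(missing)) {
    stop("unresolved reaction id(s): ", paste(missing, collapse = ", "))
  }
  reaction_ids <- unique(reaction_ids)

  roots <- names(tracer$enrichments)

  # unique producing reaction per non-root compound
  producer <- list()
  for (rid in reaction_ids) {
    rx <- model$reactions[[rid]]
    for (cid in names(rx$stoich)) {
      if (rx$stoich[[cid]] <= 0) next
      if (model$compounds[[cid]]$n_carbons == 0) next
      if (cid %in% roots) next
      if (!is.null(producer[[cid]])) {
        stop("compound '", cid, "' is produced by both '", producer[[cid]],
             "' and '", rid, "'; labelling would be ill-defined")
      }
      producer[[cid]] <- rid
    }
  }

  dists <- list()
  state <- new.env(parent = emptyenv())  # visit marks for cycle detection
  stack <- character(0)

  get_dist <- function(cid) {
    if (!is.null(dists[[cid]])) return(dists[[cid]])
    n <- model$compounds[[cid]]$n_carbons
    if (cid %in% roots) {
      p <- bernoulli_joint(tracer$enrichments[[cid]], n)
    } else {
      if (is.null(producer[[cid]])) {
        stop("compound '", cid,
             "' has no tracer specification and no producing reaction")
      }
      if (cid %in% stack) {
        cyc <- c(stack[which(stack == cid)[1]:length(stack)], cid)
        stop("cyclic labelling dependency: ", paste(cyc, collapse = " -> "))
      }
      stack <<- c(stack, cid)
      rx <- model$reactions[[producer[[cid]]]]
      tr <- rx$transitions
      tr <- tr[tr$product_compound == cid & tr$product_instance == 1L, , drop = FALSE]
      tr <- tr[order(tr$product_index), , drop = FALSE]
      if (nrow(tr) != n) {
        stop("reaction '", rx$id, "' does not source all carbons of '", cid, "'")
      }
      # group product positions by (source compound, instance)
      grp <- paste(tr$source_compound, tr$source_instance, sep = "\r")
      p <- 1
      pos_order <- integer(0)
      for (g in unique(grp)) {
        rows <- tr[grp == g, , drop = FALSE]
        src <- rows$source_compound[1]
        sd <- get_dist(src)
        marg <- marginal_joint(sd$prob, sd$n_carbons, as.integer(rows$source_index))
        p <- as.vector(outer(p, marg))  # appended positions are rows$product_index
        pos_order <- c(pos_order, rows$product_index)
      }
      # bit j of p corresponds to product position pos_order[j]; remap the
      # pattern bits to canonical position order 1..n
      q <- numeric(2^n)
      for (k in 0:(2^n - 1)) {
        bits <- bitwAnd(bitwShiftR(k, seq_len(n) - 1L), 1L)
        idx <- sum(bits * 2^(pos_order - 1L))
        q[idx + 1] <- q[idx + 1] + p[k + 1]
      }
      p <- q
      stack <<- stack[-length(stack)]
    }
    d <- structure(list(compound_id = cid, n_carbons = n,
                        prob = stats::setNames(p, pattern_names(n))),
                   class = "positional_dist")
    dists[[cid]] <<- d
    d
  }

  for (cid in names(producer)) get_dist(cid)
  dists
}

#' Collapse a positional label distribution to a mass-isotopomer distribution
#'
#' @param dist A `positional_dist` from [propagate()].
#' @return Numeric vector of length `n_carbons + 1` (fractions M+0 ... M+n),
#'   named `M0 ... Mn`.
#' @export
mid_of <- function(dist) {
  stopifnot(inherits(dist, "positional_dist"))
  n <- dist$n_carbons
  mid <- numeric(n + 1)
  for (k in 0:(2^n - 1)) {
    w <- sum(bitwAnd(bitwShiftR(k, 0:(max(n - 1, 0))), 1L))
    if (n == 0) w <- 0
    mid[w + 1] <- mid[w + 1] + dist$prob[k + 1]
  }
  stats::setNames(mid, paste0("M", 0:n))
}

#' Amino-acid metabolites reported by [predict_amino_acid_mids()]
#' @export
amino_acid_panel <- function() {
  c("glycine", "serine", "alanine", "valine", "leucine", "threonine",
    "proline", "aspartate", "PEP", "PG3")
}

#' Predict amino-acid mass-isotopomer distributions for a route
#'
#' Propagates the tracer through the route's core reactions plus the
#' biosynthetic extensions (alanine, valine, leucine, threonine via
#' oxaloacetate, proline via oxoglutarate, plus PEP/3-PG/aspartate precursor
#' proxies) and collapses each metabolite to its MID. Under an ideal formate
#' tracer the glycine-reductase route yields single-labelled pyruvate (M+1)
#' and the serine route double-labelled pyruvate (M+2), with corresponding
#' shifts in every pyruvate- and acetyl-CoA-derived amino acid.
#'
#' @param route `"GR"` or `"serine"`.
#' @param tracer A [tracer_config()].
#' @param model An `rgly_model`.
#' @param metabolites Compound ids to report (default [amino_acid_panel()]).
#' @return Named list of MID vectors.
#' @export
#' @examples
#' model <- load_pathway_model()
#' mids <- predict_amino_acid_mids("GR", tracer_config(list(formate = 1, CO2 = 0)), model)
#' mids$alanine  # point mass at M+1
predict_amino_acid_mids <- function(route = c("GR", "serine"), tracer, model,
                                    metabolites = amino_acid_panel()) {
  route <- match.arg(route)
  dists <- propagate(model$networks[[route]], tracer, model)
  unknown <- setdiff(metabolites, names(dists))
  if (length(unknown)) {
    stop("metabolite(s) not produced in the ", route, " network: ",
         paste(unknown, collapse = ", "))
  }
  lapply(stats::setNames(metabolites, metabolites),
         function(m) mid_of(dists[[m]]))
}

#' Classify the active glycine-assimilation route from observed MIDs
#'
#' Scores the observed MIDs against the predictions of the glycine-reductase
#' and serine routes (sum over metabolites of squared L2 distance, equal
#' weights) and calls the route with the smaller score, or `"ambiguous"` when
#' the score difference is below `margin`. At least one discriminating
#' metabolite (one whose two route predictions differ, e.g. the
#' pyruvate-derived amino acids) must be present.
#'
#' @param observed Named list of MID vectors (fractions M+0..M+n), or a long
#'   `data.frame` with columns `metabolite`, `m_shift`, `fraction` as read by
#'   [read_mid_csv()].
#' @param tracer A [tracer_config()] describing the experiment.
#' @param model An `rgly_model`.
#' @param margin Ambiguity threshold on `|score_GR - score_serine|`
#'   (default 1e-3).
#' @param predictions Optional precomputed predictions, a list with elements
#'   `GR` and `serine` as returned by [predict_amino_acid_mids()]; useful
#'   when classifying many datasets under one tracer.
#' @return A list of class `route_call`: `route` ("GR", "serine" or
#'   "ambiguous"), `score_GR`, `score_serine`, `margin`.
#' @export
classify_route <- function(observed, tracer, model, margin = 1e-3,
                           predictions = NULL) {
  if (is.data.frame(observed)) observed <- mids_from_long(observed)
  stopifnot(is.list(observed), !is.null(names(observed)))

  preds <- predictions %||%
    list(GR = predict_amino_acid_mids("GR", tracer, model),
         serine = predict_amino_acid_mids("serine", tracer, model))
  common <- intersect(names(observed), names(preds$GR))
  if (length(common) == 0) stop("no metabolite in common with the predictions")

  discrim <- common[vapply(common, function(m) {
    sum((preds$GR[[m]] - preds$serine[[m]])^2) > 1e-9
  }, logical(1))]
  if (length(discrim) == 0) {
    stop("no discriminating metabolite present (need a pyruvate-family ",
         "metabolite or Ser/Thr/Pro)")
  }

  score <- function(route) {
    s <- 0
    for (m in common) {
      ob <- as.numeric(observed[[m]])
      pr <- as.numeric(preds[[route]][[m]])
      if (length(ob) != length(pr)) {
        stop("observed MID for '", m, "' has length ", length(ob),
             ", expected ", length(pr))
      }
      s <- s + sum((ob - pr)^2)
    }
    s
  }
  s_gr <- score("GR")
  s_ser <- score("serine")
  route <- if (abs(s_gr - s_ser) < margin) "ambiguous"
           else if (s_gr < s_ser) "GR" else "serine"
  structure(list(route = route, score_GR = s_gr, score_serine = s_ser,
                 margin = margin),
            class = "route_call")
}

#' @export
print.route_call <- function(x, ...) {
  cat("Route call:", x$route,
      sprintf("(score GR = %.4g, serine = %.4g, margin = %g)\n",
              x$score_GR, x$score_serine, x$margin))
  invisible(x)
}

# ---- MID CSV dialect: columns metabolite, m_shift, fraction [, replicate] ----

mids_from_long <- function(df) {
  stopifnot(all(c("metabolite", "m_shift", "fraction") %in% names(df)))
  out <- list()
  for (m in unique(df$metabolite)) {
    sub <- df[df$metabolite == m, , drop = FALSE]
    sub <- sub[order(sub$m_shift), , drop = FALSE]
    v <- numeric(max(sub$m_shift) + 1)
    v[sub$m_shift + 1] <- sub$fraction
    out[[m]] <- stats::setNames(v, paste0("M", seq_along(v) - 1))
  }
  out
}

mids_to_long <- function(mids) {
  do.call(rbind, lapply(names(mids), function(m) {
    v <- as.numeric(mids[[m]])
    data.frame(metabolite = m, m_shift = seq_along(v) - 1, fraction = v,
               stringsAsFactors = FALSE)
  }))
}

#' Read / write MIDs in the package CSV dialect
#'
#' Long format with columns `metabolite`, `m_shift`, `fraction` and an
#' optional `replicate` column.
#'
#' @param path File path.
#' @return `read_mid_csv()`: a `data.frame`.
#' @export
read_mid_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "m_shift", "fraction")
  if (!all(need %in% names(df))) {
    stop("MID CSV must have columns ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_mid_csv
#' @param mids Named list of MID vectors or a long `data.frame`.
#' @export
write_mid_csv <- function(mids, path) {
  df <- if (is.data.frame(mids)) mids else mids_to_long(mids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
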