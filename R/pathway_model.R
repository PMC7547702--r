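#' Load a declarative pathway model
#'
#' Reads a YAML pathway description (compounds, reactions with per-carbon atom
#' transitions, named pathway variants and label-propagation networks) into an
#' `rgly_model` object. The package ships a model of the reductive glycine
#' pathway of *Desulfovibrio desulfuricans* with its two glycine-assimilation
#' routes (glycine reductase vs. serine), an acetate-producing variant, a
#' reductive acetyl-CoA reference pathway, and textbook biosynthetic
#' extensions used for amino-acid labelling predictions.
#'
#' @param path Path to a model YAML file. Defaults to the shipped rGly model.
#' @return An object of class `rgly_model`: a list with elements `compounds`,
#'   `reactions`, `variants` and `networks`.
#' @export
#' @examples
#' model <- load_pathway_model()
#' names(model$variants)
load_pathway_model <- function(path = system.file("extdata", "rgly_pathway.yaml",
                                                  package = "rglypath")) {
  raw <- yaml::read_yaml(path)

  compounds <- list()
  for (cp in raw$compounds) {
    roles <- as.character(unlist(cp$carbon_roles))
    if (cp$n_carbons != length(roles)) {
      stop("compound '", cp$id, "': n_carbons (", cp$n_carbons,
           ") != length(carbon_roles) (", length(roles), ")")
    }
    if (cp$id %in% names(compounds)) {
      stop("duplicate compound id '", cp$id, "'")
    }
    compounds[[cp$id]] <- list(
      id = cp$id, name = cp$name, n_carbons = as.integer(cp$n_carbons),
      carbon_roles = roles, external = isTRUE(cp$external)
    )
  }

  reactions <- list()
  for (rx in raw$reactions) {
    if (rx$id %in% names(reactions)) stop("duplicate reaction id '", rx$id, "'")
    stoich <- vapply(rx$stoich, as.numeric, numeric(1))
    unknown <- setdiff(names(stoich), names(compounds))
    if (length(unknown)) {
      stop("reaction '", rx$id, "' references unknown compound(s): ",
           paste(unknown, collapse = ", "))
    }
    reactions[[rx$id]] <- list(
      id = rx$id, name = rx$name, ec = rx$ec %||% NA_character_,
      stoich = stoich,
      atp_delta = as.numeric(rx$atp_delta),
      amp_forming = isTRUE(rx$amp_forming),
      electron_pairs = as.numeric(rx$electron_pairs),
      transitions = parse_transitions(unlist(rx$transitions), rx$id)
    )
  }

  variants <- list()
  for (v in raw$variants) {
    steps <- data.frame(
      reaction = vapply(v$steps, function(s) s$reaction, character(1)),
      flux = vapply(v$steps, function(s) as.numeric(s$flux), numeric(1)),
      stringsAsFactors = FALSE
    )
    variants[[v$name]] <- make_variant(v$name, steps, v$product,
                                       as.character(unlist(v$byproducts)))
  }

  networks <- lapply(raw$networks, function(ids) as.character(unlist(ids)))

  model <- structure(
    list(compounds = compounds, reactions = reactions,
         variants = variants, networks = networks),
    class = "rgly_model"
  )

  # refuse to load a model whose atom maps are inconsistent
  for (rx in model$reactions) {
    v <- validate_atom_maps(rx, model)
    if (length(v)) {
      stop("reaction '", rx$id, "' has invalid atom transitions:\n  ",
           paste(v, collapse = "\n  "))
    }
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a pathway variant
#'
#' @param name Variant name.
#' @param steps `data.frame` with columns `reaction` (id) and `flux`
#'   (multiplier per unit product).
#' @param product Compound id of the declared product.
#' @param byproducts Character vector of declared by-product compound ids.
#' @return An `rgly_variant` object.
#' @export
make_variant <- function(name, steps, product, byproducts = character(0)) {
  stopifnot(is.data.frame(steps), all(c("reaction", "flux") %in% names(steps)))
  structure(list(name = name, steps = steps, product = product,
                 byproducts = byproducts),
            class = "rgly_variant")
}

# Parse "product.index <- source.index" transition strings, with optional
# "#k" instance tags for reactions consuming/producing several molecules of
# the same compound. Returns a data.frame of carbon refs.
parse_transitions <- function(strings, reaction_id) {
  if (length(strings) == 0) {
    return(data.frame(product_compound = character(0),
                      product_instance = integer(0),
                      product_index = integer(0),
                      source_compound = character(0),
                      source_instance = integer(0),
                      source_index = integer(0)))
  }
  parse_ref <- function(txt) {
    m <- regmatches(txt, regexec("^([A-Za-z0-9_]+)(#([0-9]+))?\\.([0-9]+)$", txt))[[1]]
    if (length(m) == 0) {
      stop("reaction '", reaction_id, "': malformed carbon reference '", txt, "'")
    }
    list(compound = m[2],
         instance = if (m[4] == "") 1L else as.integer(m[4]),
         index = as.integer(m[5]))
  }
  parts <- lapply(strings, function(s) {
    halves <- strsplit(s, "<-", fixed = TRUE)[[1]]
    if (length(halves) != 2) {
      stop("reaction '", reaction_id, "': malformed transition '", s, "'")
    }
    p <- parse_ref(trimws(halves[1]))
    q <- parse_ref(trimws(halves[2]))
    data.frame(product_compound = p$compound, product_instance = p$instance,
               product_index = p$index,
               source_compound = q$compound, source_instance = q$instance,
               source_index = q$index, stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

# Enumerate the carbon multiset on one side of a reaction:
# one row per (compound, instance, index).
carbon_multiset <- function(reaction, model, side = c("product", "substrate")) {
  side <- match.arg(side)
  sgn <- if (side == "product") 1 else -1
  out <- list()
  for (cid in names(reaction$stoich)) {
    coef <- reaction$stoich[[cid]]
    if (sign(coef) != sgn) next
    n <- model$compounds[[cid]]$n_carbons
    if (n == 0) next
    mult <- abs(coef)
    if (mult != round(mult)) {
      stop("reaction '", reaction$id, "': non-integer stoichiometry for '",
           cid, "' cannot carry atom transitions")
    }
    for (inst in seq_len(mult)) {
      out[[length(out) + 1]] <- data.frame(
        compound = cid, instance = inst, index = seq_len(n),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(compound = character(0), instance = integer(0),
                      index = integer(0)))
  }
  do.call(rbind, out)
}

#' Validate the atom transitions of a reaction
#'
#' Checks that the transitions form a bijection over the reaction's carbon
#' multiset: every product carbon (including released CO2 carbons) has exactly
#' one source, and every substrate carbon maps to exactly one product carbon.
#'
#' @param reaction A reaction from an [load_pathway_model()] model (or a list
#'   with the same fields).
#' @param model The `rgly_model` providing compound carbon counts.
#' @return A character vector of violations; empty when the map is valid.
#' @export
validate_atom_maps <- function(reaction, model) {
  violations <- character(0)
  ref_str <- function(cmp, inst, idx) {
    paste0(cmp, if (inst != 1) paste0("#", inst) else "", ".", idx)
  }

  prods <- carbon_multiset(reaction, model, "product")
  subs <- carbon_multiset(reaction, model, "substrate")
  tr <- reaction$transitions

  key <- function(df, cmp_col, inst_col, idx_col) {
    paste(df[[cmp_col]], df[[inst_col]], df[[idx_col]], sep = "\r")
  }
  prod_keys <- key(prods, "compound", "instance", "index")
  sub_keys <- key(subs, "compound", "instance", "index")
  tr_prod <- key(tr, "product_compound", "product_instance", "product_index")
  tr_src <- key(tr, "source_compound", "source_instance", "source_index")

  # transitions must reference real carbons
  bad_p <- setdiff(tr_prod, prod_keys)
  bad_s <- setdiff(tr_src, sub_keys)
  fmt <- function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)
    vapply(parts, function(p) ref_str(p[1], as.integer(p[2]), p[3]), character(1))
  }
  if (length(bad_p)) {
    violations <- c(violations,
                    paste0("transition targets unknown product carbon ", fmt(bad_p)))
  }
  if (length(bad_s)) {
    violations <- c(violations,
                    paste0("transition uses unknown substrate carbon ", fmt(bad_s)))
  }

  cnt_p <- table(tr_prod)
  dup_p <- names(cnt_p)[cnt_p > 1]
  if (length(dup_p)) {
    violations <- c(violations,
                    paste0("duplicated source assignment for product carbon ", fmt(dup_p)))
  }
  orphan_p <- setdiff(prod_keys, tr_prod)
  if (length(orphan_p)) {
    violations <- c(violations,
                    paste0("unsourced product carbon ", fmt(orphan_p)))
  }
  cnt_s <- table(tr_src)
  dup_s <- names(cnt_s)[cnt_s > 1]
  if (length(dup_s)) {
    violations <- c(violations,
                    paste0("substrate carbon used more than once: ", fmt(dup_s)))
  }
  orphan_s <- setdiff(sub_keys, tr_src)
  if (length(orphan_s)) {
    violations <- c(violations,
                    paste0("substrate carbon unmapped: ", fmt(orphan_s)))
  }
  violations
}

resolve_variant <- function(variant, model) {
  if (is.character(variant) && length(variant) == 1) {
    if (!variant %in% names(model$variants)) {
      stop("unknown pathway variant '", variant, "'")
    }
    variant <- model$variants[[variant]]
  }
  stopifnot(inherits(variant, "rgly_variant"))
  missing <- setdiff(variant$steps$reaction, names(model$reactions))
  if (length(missing)) {
    stop("variant '", variant$name, "': unresolved reaction id(s): ",
         paste(missing, collapse = ", "))
  }
  variant
}

#' Net stoichiometry of a pathway variant
#'
#' Sums `flux * stoichiometry` over the variant's reactions and checks that
#' every non-external intermediate (anything other than the declared product,
#' declared by-products and external pools such as CO2/NH3/cofactors) cancels
#' to zero.
#'
#' @param variant An `rgly_variant` or the name of a variant in `model`.
#' @param model An `rgly_model`.
#' @return Named numeric vector of net stoichiometric coefficients (negative =
#'   consumed), including zero entries for cancelled intermediates. Empty
#'   variants give an empty vector.
#' @export
#' @examples
#' model <- load_pathway_model()
#' net_stoichiometry("rGly-GR-PTA", model)
net_stoichiometry <- function(variant, model) {
  variant <- resolve_variant(variant, model)
  net <- numeric(0)
  for (i in seq_len(nrow(variant$steps))) {
    rx <- model$reactions[[variant$steps$reaction[i]]]
    flux <- variant$steps$flux[i]
    for (cid in names(rx$stoich)) {
      net[cid] <- (if (cid %in% names(net)) net[[cid]] else 0) +
        flux * rx$stoich[[cid]]
    }
  }
  if (length(net) == 0) return(net)

  terminal <- c(variant$product, variant$byproducts)
  for (cid in names(net)) {
    cp <- model$compounds[[cid]]
    if (!cp$external && !(cid %in% terminal) && abs(net[[cid]]) > 1e-9) {
      stop("variant '", variant$name, "': intermediate '", cid,
           "' does not cancel (net ", net[[cid]], ")")
    }
  }
  # overall carbon conservation
  cnum <- vapply(names(net), function(cid) model$compounds[[cid]]$n_carbons,
                 integer(1))
  if (abs(sum(net * cnum)) > 1e-9) {
    stop("variant '", variant$name, "' does not conserve carbon")
  }
  net
}

#' Net ATP cost of a pathway variant
#'
#' Net ATP-equivalents consumed per unit product, summed as
#' `flux * atp_delta` over the variant's reactions. ATP -> ADP counts as 1
#' equivalent consumed; AMP + PPi-forming activations (acetyl-CoA synthetase)
#' count as `acs_equivalents` (2 by default, assuming pyrophosphatase
#' activity). ATP-generating steps (acetate kinase) carry negative deltas.
#'
#' @inheritParams net_stoichiometry
#' @param acs_equivalents ATP-equivalents charged to AMP-forming activations:
#'   2 (default, PPi hydrolysed) or 1.
#' @return Signed number; positive = net consumption.
#' @export
#' @examples
#' model <- load_pathway_model()
#' atp_cost("rGly-GR-PTA", model)       # 1
#' atp_cost("rGly-GR-acetate", model)   # 0
atp_cost <- function(variant, model, acs_equivalents = 2) {
  stopifnot(acs_equivalents %in% c(1, 2))
  variant <- resolve_variant(variant, model)
  if (nrow(variant$steps) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(variant$steps))) {
    rx <- model$reactions[[variant$steps$reaction[i]]]
    delta <- if (rx$amp_forming) acs_equivalents else rx$atp_delta
    total <- total + variant$steps$flux[i] * delta
  }
  total
}
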