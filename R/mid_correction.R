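#' Carbon natural-abundance correction matrix
#'
#' Builds the lower-triangular convolution matrix relating the true 13C
#' labelling of an `n`-carbon metabolite to the measured mass-isotopomer
#' distribution when the `n - j` unlabelled carbons each carry 13C at the
#' natural abundance `p13`. Entry `[i+1, j+1]` is
#' `P(measured shift i | true labelled count j) = dbinom(i - j, n - j, p13)`.
#' Columns sum to 1.
#'
#' @param n_carbons Number of carbons (>= 1).
#' @param p13 Natural 13C abundance, in `[0, 1)`; default 0.0107.
#' @return Object of class `correction_matrix` with elements `n_carbons`,
#'   `p13` and `matrix`.
#' @export
#' @examples
#' cm <- build_correction_matrix(2, 0.0107)
#' cm$matrix[1, 1]  # (1 - 0.0107)^2
build_correction_matrix <- function(n_carbons, p13 = 0.0107) {
  if (length(n_carbons) != 1 || n_carbons < 1 || n_carbons != round(n_carbons)) {
    stop("n_carbons must be a single integer >= 1")
  }
  if (p13 < 0 || p13 >= 1) stop("p13 must be in [0, 1)")
  n <- as.integer(n_carbons)
  M <- matrix(0, n + 1, n + 1,
              dimnames = list(paste0("M", 0:n), paste0("M", 0:n)))
  for (j in 0:n) {
    M[(j:n) + 1, j + 1] <- stats::dbinom(0:(n - j), n - j, p13)
  }
  structure(list(n_carbons = n, p13 = p13, matrix = M),
            class = "correction_matrix")
}

#' Forward-convolve a true MID with natural abundance
#'
#' @param mid True MID (length `n_carbons + 1`).
#' @param cm A [build_correction_matrix()] object.
#' @return The MID that would be measured.
#' @export
convolve_mid <- function(mid, cm) {
  stopifnot(inherits(cm, "correction_matrix"))
  if (length(mid) != cm$n_carbons + 1) {
    stop("MID length ", length(mid), " does not match matrix for ",
         cm$n_carbons, " carbons")
  }
  as.numeric(cm$matrix %*% as.numeric(mid))
}

#' Correct a measured MID for natural 13C abundance
#'
#' Solves `matrix %*% x ~ raw` by non-negativity-constrained least squares
#' (never returns negative fractions, robust to measurement noise) and
#' renormalizes the solution to sum to 1.
#'
#' @param raw Measured MID (length `n_carbons + 1`).
#' @param cm A [build_correction_matrix()] object.
#' @return Corrected MID: non-negative, sums to 1.
#' @export
#' @examples
#' cm <- build_correction_matrix(3)
#' x <- c(0, 1, 0, 0)
#' correct_mid(convolve_mid(x, cm), cm)  # recovers x
correct_mid <- function(raw, cm) {
  stopifnot(inherits(cm, "correction_matrix"))
  raw <- as.numeric(raw)
  if (length(raw) != cm$n_carbons + 1) {
    stop("MID length ", length(raw), " does not match matrix for ",
         cm$n_carbons, " carbons")
  }
  x <- pracma::lsqnonneg(cm$matrix, raw)$x
  s <- sum(x)
  if (s <= 0) stop("corrected MID is identically zero; cannot renormalize")
  stats::setNames(x / s, paste0("M", 0:cm$n_carbons))
}
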