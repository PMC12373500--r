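# 13C isotope tracing: natural-abundance correction of mass isotopomer
# distributions (MIDs), total labelling, enrichment normalization to
# glucose M+6, and the CitM2/PyrM3 pyruvate dehydrogenase surrogate.

#' Default natural isotope abundances
#'
#' Mass-shift probability vectors (index 0 = lightest isotope) for the
#' elements found in silylated GC-MS fragments. Values are standard
#' terrestrial abundances and can be overridden, or loaded from a
#' two-column TSV (element, comma-separated fractions) via
#' [read_abundance_table()].
#'
#' @return Named list, element -> numeric vector summing to 1.
#' @export
natural_abundances <- function() {
  list(
    C  = c(1 - 0.0107, 0.0107),
    H  = c(1 - 0.000115, 0.000115),
    N  = c(1 - 0.00364, 0.00364),
    O  = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
    Si = c(1 - 0.04685 - 0.03092, 0.04685, 0.03092),
    S  = c(1 - 0.0075 - 0.0425, 0.0075, 0.0425)
  )
}

#' @rdname natural_abundances
#' @param path TSV with columns `element` and `fractions` (comma-separated
#'   mass-shift fractions, lightest first).
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ab <- lapply(strsplit(df$fractions, ","), as.numeric)
  names(ab) <- df$element
  for (el in names(ab)) {
    if (abs(sum(ab[[el]]) - 1) > 1e-6) {
      stop(sprintf("abundance vector for %s does not sum to 1", el))
    }
  }
  ab
}

#' Parse a molecular formula string
#'
#' @param formula e.g. `"C9H20NO3Si2"`.
#' @return Named integer vector of atom counts.
#' @export
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(ifelse(grepl("[0-9]+$", toks),
                          sub("^[A-Za-z]+", "", toks), "1"))
  counts <- tapply(ct, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Fragment composition for natural-abundance correction
#'
#' @param formula Molecular formula of the measured ion (string or named
#'   count vector); elements must appear in `abundances`.
#' @param n_tracer_carbons Number of carbon positions that can carry
#'   tracer label; must not exceed the carbon count.
#' @param abundances Natural-abundance table ([natural_abundances()]).
#' @param tracer_purity Isotopic purity of the tracer (fraction of
#'   nominally labelled positions actually 13C), default 1.
#' @return List of class `"fragment_composition"`.
#' @export
fragment_composition <- function(formula, n_tracer_carbons,
                                 abundances = natural_abundances(),
                                 tracer_purity = 1) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (any(counts < 0)) stop("atom counts must be >= 0")
  unknown <- setdiff(names(counts), names(abundances))
  if (length(unknown)) {
    stop("no abundance data for element(s): ", paste(unknown, collapse = ", "))
  }
  for (el in names(abundances)) {
    if (any(abundances[[el]] < 0) || abs(sum(abundances[[el]]) - 1) > 1e-6) {
      stop(sprintf("abundance vector for %s must be nonnegative and sum to 1", el))
    }
  }
  nC <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (n_tracer_carbons > nC) {
    stop(sprintf("n_tracer_carbons (%d) exceeds carbon count (%d)",
                 n_tracer_carbons, nC))
  }
  if (tracer_purity < 0 || tracer_purity > 1) {
    stop("tracer_purity must be in [0, 1]")
  }
  structure(list(counts = counts, n_tracer_carbons = as.integer(n_tracer_carbons),
                 abundances = abundances, tracer_purity = tracer_purity),
            class = "fragment_composition")
}

# discrete convolution of two mass-shift probability vectors
conv_shift <- function(a, b) {
  if (is.null(a)) return(b)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# n-fold self-convolution of a single-atom shift pattern
atom_pattern <- function(p, n) {
  out <- 1
  for (i in seq_len(n)) out <- conv_shift(out, p)
  out
}

#' Build the natural-abundance correction matrix for a fragment
#'
#' Column j (j = 0..n tracer carbons labelled) holds the probability that
#' a molecule with exactly j tracer-derived 13C atoms is measured at mass
#' shift 0..n relative to the monoisotopic mass: the convolution of the
#' natural-abundance patterns of every atom not carrying tracer label
#' (including the n - j unlabelled tracer-position carbons), shifted by j
#' and truncated at n. The matrix is lower triangular with a positive
#' diagonal; untruncated columns sum to 1.
#'
#' @param comp A [fragment_composition()].
#' @return (n+1) x (n+1) matrix, rows = measured M+0..M+n, columns =
#'   true tracer-label count 0..n.
#' @export
build_correction_matrix <- function(comp) {
  stopifnot(inherits(comp, "fragment_composition"))
  n <- comp$n_tracer_carbons
  counts <- comp$counts
  ab <- comp$abundances
  # shift pattern of all non-carbon atoms, computed once
  base <- 1
  for (el in names(counts)) {
    if (el == "C" || counts[[el]] == 0L) next
    base <- conv_shift(base, atom_pattern(ab[[el]], counts[[el]]))
  }
  nC <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  M <- matrix(0, n + 1L, n + 1L,
              dimnames = list(paste0("M+", 0:n), paste0("lab", 0:n)))
  for (j in 0:n) {
    # unlabelled carbons: natural; labelled tracer carbons: 13C w.p. purity
    pat <- conv_shift(base, atom_pattern(ab$C, nC - j))
    if (comp$tracer_purity < 1 && j > 0) {
      pur <- atom_pattern(c(1 - comp$tracer_purity, comp$tracer_purity), j)
      pat <- conv_shift(pat, pur)
      shift <- 0L
    } else {
      shift <- j
    }
    full <- numeric(n + 1L)
    idx <- seq_along(pat) + shift
    keep <- idx <= n + 1L
    full[idx[keep]] <- pat[keep]
    M[, j + 1L] <- full
  }
  M
}

# Lawson-Hanson active-set nonnegative least squares; dimensions here are
# tiny (<= 7), so a plain R implementation is ample.
nnls_solve <- function(A, b, tol = 1e-12) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- logical(p)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * p) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(p)
      z[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(z[passive] > tol)) break
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
    }
    x <- z
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Correct a measured MID for natural isotope abundance
#'
#' Solves `M x = measured` for the tracer-only mass isotopomer
#' distribution x, where M is the [build_correction_matrix()] of the
#' fragment. `method = "nnls"` (default) uses nonnegative least squares,
#' robust to measurement noise; `method = "solve"` performs the exact
#' triangular solve and clips negatives at zero. The result is
#' renormalized to sum 1.
#'
#' @param measured Numeric vector of measured fractions M+0..M+n.
#' @param comp A [fragment_composition()] with matching tracer-carbon
#'   count.
#' @param method `"nnls"` or `"solve"`.
#' @return Corrected MID (sums to 1, entries >= 0) with the fit residual
#'   in `attr(, "residual")`.
#' @export
correct_mid <- function(measured, comp, method = c("nnls", "solve")) {
  method <- match.arg(method)
  M <- build_correction_matrix(comp)
  if (length(measured) != ncol(M)) {
    stop(sprintf("measured MID has %d entries; expected %d",
                 length(measured), ncol(M)))
  }
  condk <- kappa(M, exact = TRUE)
  if (!is.finite(condk) || condk > 1e12) {
    stop(sprintf("correction matrix is ill-conditioned (condition number %.3g)",
                 condk))
  }
  x <- switch(method,
              nnls = nnls_solve(M, measured),
              solve = pmax(forwardsolve(M, measured), 0))
  s <- sum(x)
  if (s <= 0) stop("corrected MID is identically zero")
  out <- x / s
  attr(out, "residual") <- sqrt(sum((M %*% x - measured)^2))
  names(out) <- paste0("M+", seq_along(out) - 1L)
  out
}

#' Simulate a measured MID from a true labelling distribution
#'
#' Convolves a true tracer MID with the fragment's natural-abundance
#' pattern (forward application of the correction matrix), optionally adds
#' truncated Gaussian noise, and renormalizes to sum 1.
#'
#' @param true_mid True tracer MID, length n_tracer_carbons + 1, entries
#'   >= 0 summing to 1 (tolerance 1e-9).
#' @param comp A [fragment_composition()].
#' @param noise_sd SD of additive Gaussian noise (negative values clipped
#'   at 0 before renormalization).
#' @param seed Optional integer seed.
#' @return Simulated measured MID (sums to 1).
#' @export
simulate_mid <- function(true_mid, comp, noise_sd = 0, seed = NULL) {
  if (abs(sum(true_mid) - 1) > 1e-9 || any(true_mid < 0)) {
    stop("true_mid must be nonnegative and sum to 1")
  }
  if (length(true_mid) != comp$n_tracer_carbons + 1L) {
    stop("true_mid length must equal n_tracer_carbons + 1")
  }
  if (!is.null(seed)) set.seed(seed)
  M <- build_correction_matrix(comp)
  m <- as.numeric(M %*% true_mid)
  if (noise_sd > 0) {
    m <- pmax(m + stats::rnorm(length(m), 0, noise_sd), 0)
  }
  out <- m / sum(m)
  names(out) <- paste0("M+", seq_along(out) - 1L)
  out
}

#' Total labelling of a metabolite
#'
#' The fraction of molecules carrying at least one tracer carbon,
#' `1 - M+0`.
#'
#' @param mid MID vector (fractions M+0..M+n summing to 1).
#' @return Scalar in [0, 1].
#' @export
total_labelling <- function(mid) {
  if (any(mid < -1e-9) || abs(sum(mid) - 1) > 1e-6) {
    stop("invalid MID: entries must be >= 0 and sum to 1")
  }
  1 - mid[[1L]]
}

#' Normalize labelling to glucose M+6 enrichment
#'
#' Divides labelling quantities by the [U-13C]glucose M+6 enrichment that
#' feeds them: `mode = "plasma"` scales total labelling by plasma glucose
#' M+6 (cross-patient comparability); `mode = "tumour"` scales each
#' isotopologue fraction by the same-sample tumour glucose M+6. When a
#' matched `pdx` vector is supplied alongside `patient`, PDX-minus-patient
#' differences are returned too.
#'
#' @param x Named numeric vector: total labelling values (plasma mode) or
#'   isotopologue fractions (tumour mode), e.g.
#'   `c(citrate_M2 = 0.08, pyruvate_M3 = 0.05)`.
#' @param glucose_m6 The reference glucose M+6 enrichment (> 0).
#' @param mode `"plasma"` or `"tumour"`.
#' @param pdx Optional vector matching `x` (then `x` is the patient) for
#'   paired differences.
#' @return List with `normalized` (and `pdx_normalized`, `difference` when
#'   paired).
#' @export
normalize_enrichment <- function(x, glucose_m6, mode = c("plasma", "tumour"),
                                 pdx = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(glucose_m6) || glucose_m6 <= 0) {
    stop("glucose M+6 reference must be > 0")
  }
  out <- list(normalized = x / glucose_m6, mode = mode)
  if (!is.null(pdx)) {
    stopifnot(length(pdx) == length(x))
    out$pdx_normalized <- pdx / glucose_m6
    out$difference <- out$pdx_normalized - out$normalized
  }
  out
}

#' Pyruvate dehydrogenase surrogate ratio (CitM2/PyrM3)
#'
#' Citrate M+2 over pyruvate M+3; a proxy for the contribution of
#' pyruvate dehydrogenase to TCA-cycle labelling.
#'
#' @param citrate Citrate MID (needs M+2, i.e. length >= 3).
#' @param pyruvate Pyruvate MID (needs M+3, i.e. length >= 4).
#' @return Scalar ratio >= 0.
#' @export
pdh_ratio <- function(citrate, pyruvate) {
  if (length(citrate) < 3L || length(pyruvate) < 4L) {
    stop("need citrate M+2 and pyruvate M+3 entries")
  }
  pyr_m3 <- pyruvate[[4L]]
  if (pyr_m3 <= 0) stop("pyruvate M+3 is zero: ratio undefined")
  citrate[[3L]] / pyr_m3
}
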