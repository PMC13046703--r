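#' Kernel specifications
#'
#' Constructs a validated kernel specification for Gram-matrix evaluation.
#' Five families are supported, written for row vectors `x1`, `x2`:
#'
#' * `linear`:     `x1 . x2`
#' * `polynomial`: `(c1 * x1 . x2 + c2) ^ c3`
#' * `gaussian`:   `exp(-||x1 - x2||^2 / sigma2)` (the squared distance is
#'   divided by `sigma2` directly, with no factor 2)
#' * `sigmoid`:    `tanh(a * x1 . x2 + c)`
#' * `hybrid`:     `m * linear + n * polynomial + q * gaussian` with
#'   mixture weights on the simplex (`m + n + q = 1`, each in \[0, 1\]).
#'
#' Non-integer polynomial degrees `c3 >= 1` are permitted; for non-integer
#' degrees the polynomial base is floored at zero before exponentiation so
#' fractional powers stay real (integer degrees use the raw base, so a
#' degree-1 kernel with `c1 = 1, c2 = 0` is exactly the linear kernel).
#'
#' @param family Kernel family.
#' @param c1,c2,c3 Polynomial scale, offset and degree.
#' @param sigma2 Gaussian width (variance-like, > 0).
#' @param a,c Sigmoid slope and offset.
#' @param m,n,q Hybrid mixture weights (linear, polynomial, gaussian).
#' @return An object of class `"kernel_spec"`.
#' @export
#' @examples
#' kernel_spec("hybrid", c1 = 0.0125, c2 = 3, c3 = 4, sigma2 = 10,
#'             m = 0, n = 0.4215, q = 0.5785)
kernel_spec <- function(family = c("linear", "polynomial", "gaussian",
                                   "sigmoid", "hybrid"),
                        c1 = 1, c2 = 1, c3 = 2, sigma2 = 1,
                        a = 0.01, c = 0, m = 1 / 3, n = 1 / 3, q = 1 / 3) {
  family <- match.arg(family)
  if (family %in% c("gaussian", "hybrid") && !(sigma2 > 0)) {
    stop("'sigma2' must be > 0", call. = FALSE)
  }
  if (family %in% c("polynomial", "hybrid") && c3 < 1) {
    stop("'c3' must be >= 1", call. = FALSE)
  }
  if (family == "hybrid") {
    w <- c(m, n, q)
    if (any(w < 0 | w > 1)) {
      stop("hybrid weights m, n, q must lie in [0, 1]", call. = FALSE)
    }
    if (abs(sum(w) - 1) > 1e-9) {
      stop("hybrid weights must satisfy m + n + q = 1 (|sum - 1| <= 1e-9)",
           call. = FALSE)
    }
  }
  structure(list(family = family, c1 = c1, c2 = c2, c3 = c3,
                 sigma2 = sigma2, a = a, c = c, m = m, n = n, q = q),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  pars <- switch(x$family,
    linear = "",
    polynomial = sprintf("c1 = %.4g, c2 = %.4g, c3 = %.4g", x$c1, x$c2, x$c3),
    gaussian = sprintf("sigma2 = %.4g", x$sigma2),
    sigmoid = sprintf("a = %.4g, c = %.4g", x$a, x$c),
    hybrid = sprintf(
      "c1 = %.4g, c2 = %.4g, c3 = %.4g, sigma2 = %.4g, m = %.4f, n = %.4f, q = %.4f",
      x$c1, x$c2, x$c3, x$sigma2, x$m, x$n, x$q))
  cat("Kernel: ", x$family, if (nzchar(pars)) paste0(" (", pars, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Serialize / deserialize a kernel specification
#'
#' @param x A kernel spec (`as.list`) or a named list / flat mapping with a
#'   `family` entry (`as_kernel_spec`).
#' @param ... Unused.
#' @return A plain named list, or a validated `"kernel_spec"`.
#' @export
as.list.kernel_spec <- function(x, ...) unclass(x)

#' @rdname as.list.kernel_spec
#' @export
as_kernel_spec <- function(x) {
  if (inherits(x, "kernel_spec")) return(x)
  if (is.null(x$family)) stop("'family' entry required", call. = FALSE)
  args <- x[intersect(names(x), c("family", "c1", "c2", "c3", "sigma2",
                                  "a", "c", "m", "n", "q"))]
  do.call(kernel_spec, args)
}

#' Gram matrix between two sample sets
#'
#' Evaluates the kernel on every pair of rows of `X1` and `X2`, returning
#' the `nrow(X1) x nrow(X2)` Gram matrix consumed by the SVM solver. The
#' hybrid family is the entrywise simplex-weighted sum of the linear,
#' polynomial and Gaussian Gram matrices.
#'
#' @param X1,X2 Numeric matrices with the same number of columns.
#' @param spec A [kernel_spec()].
#' @return Numeric matrix `K` with `K[i, j] = k(X1[i, ], X2[j, ])`.
#' @export
gram <- function(X1, X2 = X1, spec = kernel_spec("linear")) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) {
    stop("'X1' and 'X2' must have the same number of columns", call. = FALSE)
  }
  spec <- as_kernel_spec(spec)
  dot <- function() X1 %*% t(X2)
  sqdist <- function() {
    d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * X1 %*% t(X2)
    d2[d2 < 0] <- 0
    d2
  }
  # fractional degrees need a non-negative base to stay real; integer
  # degrees use the raw base so degree-1 kernels reduce exactly to linear
  pow <- function(base) {
    if (spec$c3 %% 1 == 0) base^spec$c3 else pmax(base, 0)^spec$c3
  }
  switch(spec$family,
    linear = dot(),
    polynomial = pow(spec$c1 * dot() + spec$c2),
    gaussian = exp(-sqdist() / spec$sigma2),
    sigmoid = tanh(spec$a * dot() + spec$c),
    hybrid = {
      d <- dot()
      spec$m * d +
        spec$n * pow(spec$c1 * d + spec$c2) +
        spec$q * exp(-sqdist() / spec$sigma2)
    })
}

#' Check positive semi-definiteness of a Gram matrix
#'
#' Mercer-validity guard: reports whether the smallest eigenvalue of a
#' symmetric Gram matrix is at least `-tolerance`. An indefinite matrix
#' (possible for the sigmoid family) raises a flag, not an error.
#'
#' @param G Square numeric matrix, symmetric within `tolerance`.
#' @param tolerance Non-negative slack on the smallest eigenvalue.
#' @return List with `psd` (logical) and `min_eigenvalue`.
#' @export
check_psd <- function(G, tolerance = 1e-8) {
  if (!is.matrix(G) || nrow(G) != ncol(G)) {
    stop("'G' must be a square matrix", call. = FALSE)
  }
  if (max(abs(G - t(G))) > max(tolerance, 1e-8) * max(1, max(abs(G)))) {
    stop("'G' is not symmetric", call. = FALSE)
  }
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(psd = min(ev) >= -tolerance, min_eigenvalue = min(ev))
}
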