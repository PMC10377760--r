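#' Radial-basis support-vector decision head
#'
#' The local classifier applied at a node once the shared network has
#' embedded a record: a kernelised decision function
#' `D(x) = sum_j gamma_j * exp(-gamma_k * ||x - d_j||^2) + m_r`
#' over support points `d_j` with signed coefficients `gamma_j`, margin
#' offset `m_r` and kernel width `gamma_k > 0`. The head is fitted on a
#' node's own data and never transmitted, so it adds no communication cost
#' and leaks nothing.
#'
#' Note the symbol clash the notation invites: the support coefficients and
#' the kernel width are distinct quantities, here `coefficients` and
#' `kernel_width`.
#'
#' @param support_points Numeric matrix of support vectors (rows).
#' @param coefficients Numeric vector, one signed coefficient per support
#'   point.
#' @param margin Scalar offset `m_r`.
#' @param kernel_width Positive RBF width `gamma_k`.
#' @return An `rsvm_head` object.
#' @export
rsvm_head <- function(support_points, coefficients, margin = 0,
                      kernel_width = 1) {
  support_points <- as.matrix(support_points)
  if (nrow(support_points) != length(coefficients))
    stop("one coefficient per support point required", call. = FALSE)
  if (kernel_width <= 0)
    stop("kernel_width must be > 0", call. = FALSE)
  structure(list(support_points = support_points,
                 coefficients = as.numeric(coefficients),
                 margin = as.numeric(margin),
                 kernel_width = as.numeric(kernel_width)),
            class = "rsvm_head")
}

#' Evaluate the kernel decision function
#'
#' @param x Numeric vector (one record) or matrix (records in rows) with
#'   the same dimension as the support points.
#' @param head An [rsvm_head()].
#' @return For a vector `x`, a list with `score` (the decision value) and
#'   `class` (1 if `score > 0`, else 0). For a matrix, a list of vectors
#'   `score` and `class`.
#' @examples
#' h <- rsvm_head(rbind(c(0, 0), c(1, 0)), c(2, -1), margin = 0.25,
#'                kernel_width = 1)
#' rsvm_decide(c(0, 0), h)  # 2*1 - 1*exp(-1) + 0.25
#' @export
rsvm_decide <- function(x, head) {
  stopifnot(inherits(head, "rsvm_head"))
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != ncol(head$support_points))
    stop("shape error: record has ", ncol(X), " features but supports have ",
         ncol(head$support_points), call. = FALSE)
  # squared distances via the expansion ||x||^2 - 2 x.d + ||d||^2
  d2 <- outer(rowSums(X^2), rep(1, nrow(head$support_points))) -
    2 * X %*% t(head$support_points) +
    outer(rep(1, nrow(X)), rowSums(head$support_points^2))
  d2[d2 < 0] <- 0
  score <- as.vector(exp(-head$kernel_width * d2) %*% head$coefficients) +
    head$margin
  cls <- as.integer(score > 0)
  if (single) list(score = score[1L], class = cls[1L])
  else list(score = score, class = cls)
}

#' Fit the decision head on local data
#'
#' Standard soft-margin dual fitting (hinge loss, RBF kernel) via
#' [e1071::svm()]; the fitted support vectors, dual coefficients and
#' offset are repackaged so the decision function is evaluated by
#' [rsvm_decide()], with the sign convention that a positive score means
#' the positive (disease) class. Features are used unscaled, matching the
#' small integer codes of the encoder.
#'
#' @param embeddings Numeric matrix of local records or their network
#'   embeddings (rows).
#' @param labels Binary vector in `{0, 1}`; both classes must be present.
#' @param kernel_width Positive RBF width `gamma_k`.
#' @param regularization Soft-margin cost parameter.
#' @return An [rsvm_head()].
#' @export
fit_rsvm_head <- function(embeddings, labels, kernel_width = 1,
                          regularization = 1) {
  X <- as.matrix(embeddings)
  if (nrow(X) < 2L)
    stop("fit error: need at least 2 records", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("fit error: both classes must be present", call. = FALSE)
  y <- factor(labels, levels = c(0, 1))
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    gamma = kernel_width, cost = regularization,
                    scale = FALSE)
  # orient the decision sign so that positive score means class 1: the
  # fitted decision value is positive for the class named first in the
  # "A/B" decision-value column
  dv <- stats::predict(fit, X[1, , drop = FALSE], decision.values = TRUE)
  pos_class <- strsplit(colnames(attr(dv, "decision.values")), "/")[[1]][1]
  s <- if (pos_class == "1") 1 else -1
  rsvm_head(fit$SV, s * as.vector(fit$coefs), margin = -s * fit$rho,
            kernel_width = kernel_width)
}
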