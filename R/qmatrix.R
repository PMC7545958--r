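#' Validate and construct a Q-matrix
#'
#' A Q-matrix is the J x K binary design matrix of a cognitive diagnostic
#' model: `q[j, k] = 1` means a correct response to item `j` requires
#' attribute `k`.  The constructor checks the structural requirements and
#' attaches the per-item required-attribute count \eqn{K^*_j = \sum_k q_{jk}}.
#'
#' Identifiability of the Q-matrix is *not* checked; completeness and
#' identifiability conditions should be verified externally before
#' estimation.
#'
#' @param x integer matrix (or object coercible to one) of 0/1 entries,
#'   items in rows, attributes in columns.
#' @return An object of class `"qmatrix"`: the binary matrix with
#'   attributes `Kstar` (integer vector of length J), and dimensions
#'   accessible via `nrow()`/`ncol()`.
#' @examples
#' Q <- validate_qmatrix(diag(3))
#' attr(Q, "Kstar")
#' @export
validate_qmatrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("Q-matrix must be numeric")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("Q-matrix must have J >= 1 and K >= 1")
  if (anyNA(x)) stop("Q-matrix has missing entries")
  if (!all(x %in% c(0, 1))) stop("Q-matrix entries must be 0 or 1")
  storage.mode(x) <- "integer"
  Kstar <- as.integer(rowSums(x))
  if (any(Kstar == 0L)) {
    stop("item(s) ", paste(which(Kstar == 0L), collapse = ", "),
         " require no attribute (all-zero row)")
  }
  if (any(colSums(x) == 0L)) {
    stop("attribute(s) ", paste(which(colSums(x) == 0L), collapse = ", "),
         " are required by no item (all-zero column)")
  }
  dimnames(x) <- NULL
  structure(x, Kstar = Kstar, class = c("qmatrix", "matrix", "array"))
}

#' @export
print.qmatrix <- function(x, ...) {
  cat(sprintf("Q-matrix: %d items x %d attributes (K*_j range %d-%d)\n",
              nrow(x), ncol(x), min(attr(x, "Kstar")), max(attr(x, "Kstar"))))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Enumerate all attribute profiles
#'
#' Returns the \eqn{2^K} binary attribute profiles (latent classes) in
#' binary-counting order with attribute 1 as the least-significant bit:
#' row `c + 1` is the profile whose k-th entry is bit `k - 1` of `c`.
#' This ordering is stable across the package; posterior class summaries
#' index classes by it.
#'
#' @param K number of attributes (1 to 15).
#' @return `2^K x K` integer matrix of 0/1 profiles.
#' @examples
#' latent_classes(2)
#' @export
latent_classes <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L || K > 15L) stop("K must be an integer in 1..15")
  cls <- 0:(2^K - 1L)
  m <- matrix(0L, nrow = 2^K, ncol = K)
  for (k in seq_len(K)) m[, k] <- bitwAnd(cls %/% 2L^(k - 1L), 1L)
  m
}

#' Reduced attribute profile for one item
#'
#' The reduced profile \eqn{\alpha^*_j} keeps only the attributes the
#' item requires (positions with `q[j, k] = 1`).
#'
#' @param alpha binary attribute vector of length K.
#' @param qrow binary Q-matrix row for the item.
#' @return binary vector of length \eqn{K^*_j}.
#' @export
reduced_profile <- function(alpha, qrow) {
  stopifnot(length(alpha) == length(qrow))
  alpha[qrow == 1]
}

#' Mastery indicator matrix over all latent classes
#'
#' For each latent class and item, whether the class "masters" the item
#' under the given condensation rule: DINA requires all of the item's
#' attributes, DINO at least one.
#'
#' @param qmatrix a [validate_qmatrix()] object (or binary matrix).
#' @param model "DINA" or "DINO".
#' @return `2^K x J` integer 0/1 matrix, classes in [latent_classes()] order.
#' @keywords internal
mastery_matrix <- function(qmatrix, model = c("DINA", "DINO")) {
  model <- match.arg(model)
  Q <- validate_qmatrix(qmatrix)
  cls <- latent_classes(ncol(Q))
  hits <- cls %*% t(unclass(Q))          # number of required attributes mastered
  if (model == "DINA") {
    m <- sweep(hits, 2L, attr(Q, "Kstar"), `>=`)
  } else {
    m <- hits >= 1L
  }
  storage.mode(m) <- "integer"
  m
}

#' Read / write a Q-matrix
#'
#' Q-matrices travel as headerless delimited text (comma or tab),
#' J rows x K columns of 0/1.
#'
#' @param path file path.
#' @param sep field separator; `read_qmatrix` sniffs comma vs tab when
#'   not given.
#' @return `read_qmatrix`: a validated `"qmatrix"`; `write_qmatrix`:
#'   `path`, invisibly.
#' @export
read_qmatrix <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  x <- utils::read.table(path, sep = sep, header = FALSE)
  validate_qmatrix(as.matrix(x))
}

#' @param qmatrix object to write.
#' @rdname read_qmatrix
#' @export
write_qmatrix <- function(qmatrix, path, sep = ",") {
  Q <- validate_qmatrix(qmatrix)
  utils::write.table(unclass(Q), path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' The 30 x 5 simulation-design Q-matrix
#'
#' The Q-matrix used by the package's standard simulation designs: five
#' attributes, 30 items; items 1-10 require one attribute, 11-20 two,
#' 21-30 three, with each attribute appearing in a balanced rotation.
#'
#' @return a `"qmatrix"` of dimension 30 x 5.
#' @seealso [study1_design()]
#' @export
sim_qmatrix <- function() {
  rows <- c(
    "10000", "01000", "00100", "00010", "00001",
    "10000", "01000", "00100", "00010", "00001",
    "11000", "10100", "10010", "10001", "01100",
    "01010", "01001", "00110", "00101", "00011",
    "11100", "11010", "11001", "10110", "10101",
    "10011", "01110", "01101", "01011", "00111")
  m <- t(vapply(strsplit(rows, ""), function(r) as.integer(r), integer(5)))
  validate_qmatrix(m)
}
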