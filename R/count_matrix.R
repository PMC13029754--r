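#' Gene-by-sample count matrix for one symbiotic partner
#'
#' Light container around an integer matrix of gene-level read counts for a
#' single partner of the nodule (the plant host or the rhizobial symbiont).
#' Rows are genes, columns are samples; both sets of identifiers must be
#' unique and counts must be non-negative integers.
#'
#' @param counts Numeric matrix of non-negative integers with unique
#'   rownames (gene ids) and colnames (sample ids); at least 1 gene and
#'   2 samples.
#' @param partner `"host"` or `"symbiont"`.
#' @return An object of class `count_matrix`: the validated integer matrix
#'   with attribute `partner`.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' count_matrix(m, "host")
#' @export
count_matrix <- function(counts, partner = c("host", "symbiont")) {
  partner <- match.arg(partner)
  if (!is.matrix(counts)) {
    counts <- as.matrix(counts)
  }
  validate_counts(counts)
  storage.mode(counts) <- "integer"
  structure(counts, partner = partner, class = c("count_matrix", class(counts)))
}

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample id(s)", call. = FALSE)
  }
  if (nrow(counts) < 1L || ncol(counts) < 2L) {
    stop("count matrix needs >= 1 gene and >= 2 samples", call. = FALSE)
  }
  if (anyNA(counts)) stop("count matrix contains missing values", call. = FALSE)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (any(counts < 0)) stop("negative count(s) found", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("non-integer count(s) found", call. = FALSE)
  }
  invisible(counts)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s partner)\n",
              nrow(x), ncol(x), partner_of(x)))
  cat("library sizes:", paste(colSums(x), collapse = " "), "\n")
  invisible(x)
}

#' Partner of a count matrix
#'
#' @param x A [count_matrix()].
#' @return `"host"`, `"symbiont"`, or `NA` when unset.
#' @export
partner_of <- function(x) {
  p <- attr(x, "partner")
  if (is.null(p)) NA_character_ else p
}

#' Library sizes (column sums) of a count matrix
#'
#' @param counts A count matrix.
#' @return Named numeric vector of per-sample total counts.
#' @export
lib_sizes <- function(counts) {
  colSums(unclass(counts))
}
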