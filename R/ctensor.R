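#' Complex tensors with named axes
#'
#' A `ctensor` is a plain R complex array carrying a character vector of
#' unique axis names (attribute `"axes"`), one per array dimension. All
#' network and physics operations in the package address axes by name, so
#' storage order is an implementation detail.
#'
#' @param values numeric or complex array (or vector with `dim` set).
#' @param axes character vector of axis names, one per dimension.
#' @return A complex array of class `ctensor`.
#' @examples
#' x <- ctensor(array(1:6, c(2, 3)), c("RO", "PE"))
#' ct_axes(x)
#' @export
ctensor <- function(values, axes) {
  if (is.null(dim(values))) dim(values) <- length(values)
  if (length(axes) != length(dim(values)))
    stop("need one axis name per array dimension")
  if (anyDuplicated(axes)) stop("axis names must be unique within a tensor")
  v <- values
  if (!is.complex(v)) v <- v + 0i
  attr(v, "axes") <- as.character(axes)
  class(v) <- c("ctensor", class(v))
  v
}

#' @rdname ctensor
#' @param x a `ctensor`.
#' @export
ct_axes <- function(x) {
  a <- attr(x, "axes")
  if (is.null(a)) stop("not a ctensor: no axis names")
  a
}

# internal fast constructor: no coercion or validation
new_ct <- function(v, axes) {
  attr(v, "axes") <- axes
  class(v) <- c("ctensor", class(v))
  v
}

#' Permute a ctensor to a given axis order
#'
#' @param x a `ctensor`.
#' @param axes character vector: permutation of `ct_axes(x)`.
#' @return the permuted `ctensor`.
#' @export
ct_perm <- function(x, axes) {
  a <- ct_axes(x)
  if (!setequal(a, axes) || length(a) != length(axes))
    stop("axes must be a permutation of the tensor's axes")
  if (identical(a, as.character(axes))) return(x)
  v <- aperm(unclass(x), match(axes, a))
  new_ct(v, as.character(axes))
}

#' Named axis lengths of a ctensor
#' @param x a `ctensor`.
#' @return named integer vector of axis lengths.
#' @export
ct_dim <- function(x) {
  d <- dim(x)
  names(d) <- ct_axes(x)
  d
}

# drop length-1 axes (all by default); internal
ct_squeeze <- function(x, axes = NULL) {
  d <- ct_dim(x)
  drop_ax <- if (is.null(axes)) names(d)[d == 1L] else axes
  keep <- !(names(d) %in% drop_ax)
  if (all(keep)) return(x)
  if (any(d[!keep] != 1L)) stop("can only squeeze length-1 axes")
  v <- unclass(x)
  dim(v) <- unname(d[keep])
  ctensor(v, names(d)[keep])
}

#' @export
print.ctensor <- function(x, ...) {
  d <- ct_dim(x)
  cat("<ctensor> ", paste(sprintf("%s=%d", names(d), d), collapse = " x "),
      "\n", sep = "")
  invisible(x)
}

# run expr with a private RNG stream; global RNG state is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# standard complex gaussian draws, sd per real component
rcnorm <- function(n, sd = 1) complex(real = stats::rnorm(n, 0, sd),
                                      imaginary = stats::rnorm(n, 0, sd))
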