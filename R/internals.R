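# Internal canonical encodings and small utilities.
#
# Nodes are interned structurally: a node is the universal-ancestor (UA) node
# or a (label, subpartition) pair, and two nodes are the same node iff their
# canonical keys are equal.  Canonical keys are built with three control
# characters as separators, which are therefore forbidden inside labels.

.SEP_L <- "\u001f" # between labels inside a clade, and inside a clade-union string
.SEP_C <- "\u001e" # between clades inside a subpartition string
.SEP_K <- "\u001d" # between label and subpartition string in a node key
.UA_KEY <- "\u0011UA"

# radix sort: C-locale, platform- and locale-independent ordering
.rsort <- function(x) sort.int(x, method = "radix")

.checkLabels <- function(x) {
  bad <- grepl("[\u001d\u001e\u001f]", x)
  if (any(bad))
    .sdagStop("BAD_LABEL", "labels must not contain control characters U+001D..U+001F")
  if (anyNA(x) || any(!nzchar(x)))
    .sdagStop("BAD_LABEL", "labels must be nonempty, non-NA strings")
  invisible(x)
}

.cladeStr <- function(members) paste(members, collapse = .SEP_L)

# Canonicalize and validate a subpartition given as a list of character
# vectors of leaf labels.  Errors: EMPTY_CLADE, SINGLETON, OVERLAP.
.canonClades <- function(clades) {
  if (length(clades) == 0L) return(list())
  cl <- lapply(clades, function(m) .rsort(unique(as.character(m))))
  if (any(vapply(cl, length, 0L) == 0L))
    .sdagStop("EMPTY_CLADE", "clades in a subpartition must be nonempty")
  for (m in cl) .checkLabels(m)
  strs <- vapply(cl, .cladeStr, "")
  cl <- cl[!duplicated(strs)]
  strs <- strs[!duplicated(strs)]
  if (length(cl) == 1L)
    .sdagStop("SINGLETON", "a subpartition may not consist of exactly one clade")
  all_members <- unlist(cl)
  if (anyDuplicated(all_members))
    .sdagStop("OVERLAP", "clades in a subpartition must be pairwise disjoint")
  cl[order(strs, method = "radix")]
}

.partStr <- function(clades) paste(vapply(clades, .cladeStr, ""), collapse = .SEP_C)

.nodeKeyOf <- function(label, clades) paste(label, .partStr(clades), sep = .SEP_K)

# serialized clade union of a non-UA node with canonical clades
.cuStrOf <- function(label, clades) {
  if (length(clades) == 0L) return(label)
  .cladeStr(.rsort(unlist(clades)))
}

.splitCU <- function(cu) strsplit(cu, .SEP_L, fixed = TRUE)[[1]]

# structured conditions: class c("sdag_<CODE>", "sdagError", ...)
.sdagStop <- function(code, msg) {
  stop(structure(
    class = c(paste0("sdag_", code), "sdagError", "error", "condition"),
    list(message = sprintf("[%s] %s", code, msg), call = sys.call(-1L))
  ))
}

## ---- exact nonnegative big integers (base 1e7 digit vectors) ----

.BN_BASE <- 1e7

.bn <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) == 1L, !is.na(x), x >= 0, x == floor(x), x < 2^53)
  d <- numeric(0)
  repeat {
    d <- c(d, x %% .BN_BASE)
    x <- floor(x / .BN_BASE)
    if (x == 0) break
  }
  structure(d, class = "bignat")
}

.bnNorm <- function(d) {
  carry <- 0
  i <- 1L
  while (i <= length(d) || carry > 0) {
    if (i > length(d)) d[i] <- 0
    v <- d[i] + carry
    d[i] <- v %% .BN_BASE
    carry <- floor(v / .BN_BASE)
    i <- i + 1L
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  structure(d, class = "bignat")
}

.bnAdd <- function(a, b) {
  n <- max(length(a), length(b))
  av <- c(unclass(a), numeric(n - length(a)))
  bv <- c(unclass(b), numeric(n - length(b)))
  .bnNorm(av + bv)
}

.bnMul <- function(a, b) {
  av <- unclass(a); bv <- unclass(b)
  res <- numeric(length(av) + length(bv))
  for (i in seq_along(av)) {
    if (av[i] == 0) next
    idx <- i:(i + length(bv) - 1L)
    res[idx] <- res[idx] + av[i] * bv
    # partial carry keeps every entry well below 2^53
    res <- unclass(.bnNorm(res))
  }
  .bnNorm(res)
}

# -1, 0, 1 for a < b, a == b, a > b
.bnCmp <- function(a, b) {
  av <- unclass(a); bv <- unclass(b)
  if (length(av) != length(bv)) return(sign(length(av) - length(bv)))
  for (i in rev(seq_along(av))) {
    if (av[i] != bv[i]) return(sign(av[i] - bv[i]))
  }
  0L
}

# mantissa/exponent approximation for sampling weights: value ~= m * 10^e
.bnApprox <- function(a) {
  d <- unclass(a)
  n <- length(d)
  m <- d[n]
  if (n >= 2L) m <- m + d[n - 1L] / .BN_BASE
  if (n >= 3L) m <- m + d[n - 2L] / .BN_BASE^2
  c(m = m, e = (n - 1L) * 7)
}

#' @export
as.character.bignat <- function(x, ...) {
  d <- unclass(x)
  top <- format(d[length(d)], scientific = FALSE)
  rest <- if (length(d) > 1L) sprintf("%07.0f", rev(d[-length(d)])) else character(0)
  paste0(top, paste(rest, collapse = ""))
}

#' @export
as.double.bignat <- function(x, ...) {
  d <- unclass(x)
  sum(d * .BN_BASE^(seq_along(d) - 1L))
}

#' @export
format.bignat <- function(x, ...) as.character(x)

#' @export
print.bignat <- function(x, ...) {
  cat(as.character(x), "\n", sep = "")
  invisible(x)
}

## ---- seeded evaluation without clobbering the caller's RNG stream ----

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
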