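## Minimal arbitrary-precision non-negative integers.
##
## nTABS and M = prod(m_i) can exceed 2^53, and no big-integer package is
## available, so the few operations Burnside counting needs are implemented
## here: construction, addition, multiplication by a small integer, exact
## division by a small integer, comparison and formatting.  Digits are stored
## little-endian in base 1e7 as doubles (1e7 * small factor stays well below
## 2^53, so all intermediate products are exact).

.BI_BASE <- 1e7

#' Arbitrary-precision non-negative integer
#'
#' Constructs a `tabsBigInt`, the exact integer type used for set
#' cardinalities and nTABS values, which routinely exceed the range of R
#' doubles for flexible molecules.  Accepts a non-negative numeric that is
#' exactly representable (integer-valued, below 2^53) or a decimal digit
#' string of any length.
#'
#' @param x a single non-negative integer-valued numeric, a decimal string,
#'   or an existing `tabsBigInt` (returned unchanged).
#' @return an object of class `tabsBigInt`.
#' @examples
#' bigInteger("123456789012345678901234567890")
#' bigInteger(42) * 7L
#' @export
bigInteger <- function(x) {
  if (inherits(x, "tabsBigInt")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L, grepl("^[0-9]+$", x))
    x <- sub("^0+(?=.)", "", x, perl = TRUE)
    n <- nchar(x)
    starts <- rev(seq(n, 1L, by = -7L))
    digs <- rev(vapply(starts, function(s) {
      as.numeric(substr(x, max(1L, s - 6L), s))
    }, numeric(1)))
    return(.bi(digs))
  }
  stopifnot(is.numeric(x), length(x) == 1L, !is.na(x), x >= 0,
            x == trunc(x), x < 2^53)
  digs <- numeric(0)
  x <- as.numeric(x)
  repeat {
    digs <- c(digs, x %% .BI_BASE)
    x <- (x - x %% .BI_BASE) / .BI_BASE
    if (x == 0) break
  }
  .bi(digs)
}

.bi <- function(digits) {
  # strip leading (high-order) zeros; canonical zero is a single 0 digit
  while (length(digits) > 1L && digits[length(digits)] == 0) {
    digits <- digits[-length(digits)]
  }
  structure(list(digits = digits), class = "tabsBigInt")
}

.bi_carry <- function(digits) {
  carry <- 0
  out <- numeric(length(digits))
  for (i in seq_along(digits)) {
    v <- digits[i] + carry
    out[i] <- v %% .BI_BASE
    carry <- (v - out[i]) / .BI_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% .BI_BASE)
    carry <- (carry - carry %% .BI_BASE) / .BI_BASE
  }
  .bi(out)
}

biAdd <- function(a, b) {
  a <- bigInteger(a); b <- bigInteger(b)
  n <- max(length(a$digits), length(b$digits))
  da <- c(a$digits, numeric(n - length(a$digits)))
  db <- c(b$digits, numeric(n - length(b$digits)))
  .bi_carry(da + db)
}

# multiply by a small non-negative integer k (k < 2^45 keeps products exact)
biMulSmall <- function(a, k) {
  a <- bigInteger(a)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0, k == trunc(k), k < 2^45)
  if (k == 0) return(bigInteger(0))
  .bi_carry(a$digits * k)
}

# exact division by small positive integer; errors unless remainder is zero
# (the zero-remainder assertion is Burnside's own self-check)
biDivSmallExact <- function(a, k) {
  qr <- biDivModSmall(a, k)
  if (qr$remainder != 0) {
    stop("division is not exact (remainder ", qr$remainder, ")", call. = FALSE)
  }
  qr$quotient
}

biDivModSmall <- function(a, k) {
  a <- bigInteger(a)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k == trunc(k), k < 2^45)
  rem <- 0
  out <- numeric(length(a$digits))
  for (i in rev(seq_along(a$digits))) {
    cur <- rem * .BI_BASE + a$digits[i]
    out[i] <- (cur - cur %% k) / k
    rem <- cur %% k
  }
  list(quotient = .bi(out), remainder = rem)
}

# -1, 0, 1 as a is <, ==, > b
biCompare <- function(a, b) {
  a <- bigInteger(a); b <- bigInteger(b)
  la <- length(a$digits); lb <- length(b$digits)
  if (la != lb) return(if (la < lb) -1L else 1L)
  for (i in rev(seq_len(la))) {
    if (a$digits[i] != b$digits[i]) {
      return(if (a$digits[i] < b$digits[i]) -1L else 1L)
    }
  }
  0L
}

#' @export
as.character.tabsBigInt <- function(x, ...) {
  d <- rev(x$digits)
  paste0(d[1], paste(sprintf("%07.0f", d[-1]), collapse = ""))
}

#' @export
format.tabsBigInt <- function(x, ...) as.character(x)

#' @export
print.tabsBigInt <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

#' @export
as.double.tabsBigInt <- function(x, ...) {
  sum(x$digits * .BI_BASE^(seq_along(x$digits) - 1))
}

#' @export
Ops.tabsBigInt <- function(e1, e2) {
  switch(.Generic,
    "+" = biAdd(e1, e2),
    "*" = .bi_times(e1, e2),
    "==" = biCompare(e1, e2) == 0L,
    "!=" = biCompare(e1, e2) != 0L,
    "<" = biCompare(e1, e2) < 0L,
    "<=" = biCompare(e1, e2) <= 0L,
    ">" = biCompare(e1, e2) > 0L,
    ">=" = biCompare(e1, e2) >= 0L,
    stop("operation '", .Generic, "' not supported for tabsBigInt",
         call. = FALSE))
}

.bi_times <- function(e1, e2) {
  if (inherits(e2, "tabsBigInt") && !inherits(e1, "tabsBigInt")) {
    tmp <- e1; e1 <- e2; e2 <- tmp
  }
  if (inherits(e2, "tabsBigInt")) {
    # full big x big product, digit by digit (rarely needed, sizes are small)
    acc <- bigInteger(0)
    for (i in seq_along(e2$digits)) {
      term <- biMulSmall(e1, e2$digits[i])
      if (i > 1L) term <- .bi(c(numeric(i - 1L), term$digits))
      acc <- biAdd(acc, term)
    }
    return(acc)
  }
  biMulSmall(e1, e2)
}

# product of a plain vector of small positive integers, as tabsBigInt
biProduct <- function(values) {
  acc <- bigInteger(1)
  for (v in values) acc <- biMulSmall(acc, v)
  acc
}
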