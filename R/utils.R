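#' @importFrom stats median runmed quantile lm coef setNames complete.cases
#' @importFrom utils read.delim write.table head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N (case-insensitive).
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Vectorised reverse complement.
revcomp_all <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Rotate a sequence so that 0-based position `pos` becomes the new origin.
rotate_seq <- function(x, pos) {
  n <- nchar(x)
  pos <- ((pos %% n) + n) %% n
  if (pos == 0) return(x)
  paste0(substr(x, pos + 1L, n), substr(x, 1L, pos))
}

# TRUE if b is an exact rotation of a, or of revcomp(a).
is_rotation_or_flip <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  if (grepl(b, paste0(a, a), fixed = TRUE)) return(TRUE)
  grepl(b, paste0(revcomp(a), revcomp(a)), fixed = TRUE)
}

# All k-mers of a string as a character vector (positions 1..n-k+1).
kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

# Random DNA of length n with the given GC fraction.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Hamming distance between two equal-length strings.
str_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Round half-up to `digits` decimals (Table-style fixed-point rounding).
round_half_up <- function(x, digits) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Force an odd integer >= 3 (for runmed windows).
odd_at_least <- function(x, lo = 3L) {
  x <- max(as.integer(round(x)), lo)
  if (x %% 2L == 0L) x + 1L else x
}

# Circular running median: wrap-pad so the filter is exactly
# rotation-equivariant.
circ_runmed <- function(x, w) {
  w <- odd_at_least(w)
  n <- length(x)
  if (w >= n) return(rep(median(x), n))
  h <- (w - 1L) %/% 2L
  padded <- c(tail(x, h), x, head(x, h))
  as.numeric(runmed(padded, w, endrule = "keep")[(h + 1L):(h + n)])
}

# Contiguous TRUE runs in a logical vector; circular vectors are handled by
# doubling and de-duplicating modulo n. Returns a data.frame with 0-based
# half-open [start, end) coordinates (end may exceed n for wrapping runs).
logical_runs <- function(mask, circular = FALSE) {
  n <- length(mask)
  empty <- data.frame(start = integer(0), end = integer(0), len = integer(0))
  if (!any(mask)) return(empty)
  if (circular && all(mask)) {
    return(data.frame(start = 0L, end = n, len = n))
  }
  m <- if (circular) c(mask, mask) else mask
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  out <- data.frame(start = starts[keep], end = ends[keep])
  if (circular) {
    # runs are detected on the doubled mask; keep those starting in the
    # first copy, and drop the truncated start-of-vector duplicate of a
    # run that wraps the origin
    out <- out[out$start < n, , drop = FALSE]
    if (any(out$end > n) && any(out$start == 0L)) {
      out <- out[out$start != 0L, , drop = FALSE]
    }
  }
  out$len <- out$end - out$start
  rownames(out) <- NULL
  out
}

# Longest strictly increasing subsequence length (patience sorting).
lis_length <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  tails <- numeric(0)
  for (v in x) {
    # strict LIS: binary-search the first tail >= v and replace it
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (tails[mid] < v) lo <- mid + 1L else hi <- mid
    }
    tails[lo] <- v
  }
  length(tails)
}
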