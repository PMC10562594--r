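#' Damerau-Levenshtein (optimal string alignment) distance
#'
#' Edit distance counting insertions, deletions, substitutions and
#' transpositions of adjacent characters, in the optimal-string-alignment
#' variant used by most spell-matching toolkits. Used to map typed recall
#' responses onto a restricted vocabulary; base R's [utils::adist()] lacks
#' the transposition operation, which is the most common typing slip.
#'
#' @param a,b character vectors; `b` is recycled against `a` element-wise
#'   when one of them has length 1.
#' @return integer vector of distances.
#' @examples
#' dl_distance("atomm", "atom")   # 1 deletion
#' dl_distance("piolt", "pilot")  # 1 transposition
#' @export
dl_distance <- function(a, b) {
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  mapply(dl_distance1, a, b, USE.NAMES = FALSE)
}

dl_distance1 <- function(a, b) {
  s <- utf8ToInt(a)
  t <- utf8ToInt(b)
  n <- length(s)
  m <- length(t)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  # three rolling rows of the OSA dynamic programme
  prev2 <- integer(m + 1L)
  prev1 <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cost <- if (s[i] == t[j]) 0L else 1L
      d <- min(cur[j] + 1L, prev1[j + 1L] + 1L, prev1[j] + cost)
      if (i > 1L && j > 1L && s[i] == t[j - 1L] && s[i - 1L] == t[j]) {
        d <- min(d, prev2[j - 1L] + 1L)
      }
      cur[j + 1L] <- d
    }
    prev2 <- prev1
    prev1 <- cur
  }
  prev1[m + 1L]
}
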