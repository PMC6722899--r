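# Brute-force oracles, deliberately naive: they enumerate candidates by
# direct substring reconstruction and are used to pin down expected values
# independently of the package's prefix/suffix and diagonal-scan
# implementations.

DNA <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

# every donor d (0..nV) such that deleting reference[d+1 .. d+del] yields
# the variant; canonical call = max donor, ambiguity = family width - 1
oracle_linear <- function(ref, var, min_anchor) {
  nR <- nchar(ref); nV <- nchar(var)
  if (nV > nR) return(list(status = "not_deletion"))
  if (identical(ref, var)) return(list(status = "none"))
  del <- nR - nV
  valid <- Filter(function(d)
    paste0(substr(ref, 1, d), substr(ref, d + del + 1, nR)) == var, 0:nV)
  if (!length(valid)) return(list(status = "reject"))
  d <- max(unlist(valid))
  if (d < min_anchor || nV - d < min_anchor) return(list(status = "anchor"))
  amb <- length(valid) - 1L
  list(status = "call", donor = d, acceptor = d + del + 1L, deletion_len = del,
       ambiguity = amb, repeat_seq = if (amb) substr(ref, d - amb + 1, d) else "")
}

# all (donor, acceptor <= donor) pairs over all read splits with both arms
# matching by direct substring comparison; repeat-equivalent pairs are
# collapsed by sliding to max donor
oracle_backsplice <- function(ref, read, min_anchor) {
  nR <- nchar(ref); nQ <- nchar(read)
  if (nQ >= nR) return(list(status = "too_long"))
  for (st in seq_len(nR - nQ + 1))
    if (substr(ref, st, st + nQ - 1) == read) return(list(status = "none"))
  pairs <- list()
  for (i in seq_len(nQ)) {
    if (i < min_anchor || nQ - i < min_anchor) next
    r1 <- substr(read, 1, i); r2 <- substr(read, i + 1, nQ)
    for (d in i:nR) {
      if (substr(ref, d - i + 1, d) != r1) next
      for (a in 1:d) {
        if (a + (nQ - i) - 1 <= nR && substr(ref, a, a + nQ - i - 1) == r2)
          pairs[[length(pairs) + 1]] <- c(d, a)
      }
    }
  }
  if (!length(pairs)) return(list(status = "reject"))
  slid <- unique(lapply(pairs, function(da) {
    d <- da[1]; a <- da[2]
    while (d < nR && substr(ref, d + 1, d + 1) == substr(ref, a, a))
      { d <- d + 1L; a <- a + 1L }
    as.integer(c(d, a))
  }))
  if (length(slid) > 1) return(list(status = "ambiguous", n = length(slid)))
  d <- slid[[1]][1]; a <- slid[[1]][2]
  # ambiguity = number of alternative placements reachable by sliding left
  amb <- 0L
  while (d - amb - 1 >= 1 && a - amb - 1 >= 1 &&
         substr(ref, d - amb, d - amb) == substr(ref, a - amb - 1, a - amb - 1))
    amb <- amb + 1L
  list(status = "call", donor = d, acceptor = a, ambiguity = amb,
       repeat_seq = if (amb) substr(ref, d - amb + 1, d) else "")
}

# all common substrings by full enumeration, longest wins; ties by start1
# then start2
oracle_lcs <- function(s1, s2) {
  n <- nchar(s1); m <- nchar(s2)
  for (L in min(n, m):1) {
    best <- NULL
    for (i in 1:(n - L + 1)) {
      sub <- substr(s1, i, i + L - 1)
      for (j in 1:(m - L + 1)) {
        if (substr(s2, j, j + L - 1) == sub) {
          if (is.null(best) || i < best$start1 ||
              (i == best$start1 && j < best$start2))
            best <- list(string = sub, length = L, start1 = i, start2 = j)
          break  # smallest j for this i
        }
      }
    }
    if (!is.null(best)) return(best)
  }
  list(string = "", length = 0L, start1 = NA, start2 = NA)
}

rc_chr <- function(s) splicesleuth::reverse_complement(s)

# all reverse-complement substring pairs of any length; maximal = not
# contained in a one-step extension on either side
oracle_rc_matches <- function(s1, s2, min_len) {
  n <- nchar(s1); m <- nchar(s2)
  key <- function(i, j, L) paste(i, j, L)
  all_pairs <- new.env()
  hits <- list()
  for (L in 1:min(n, m)) for (i in 1:(n - L + 1)) {
    sub1 <- substr(s1, i, i + L - 1); rc1 <- rc_chr(sub1)
    for (j in 1:(m - L + 1)) {
      if (substr(s2, j, j + L - 1) == rc1) {
        assign(key(i, j, L), TRUE, envir = all_pairs)
        hits[[length(hits) + 1]] <- list(i = i, j = j, L = L)
      }
    }
  }
  keep <- Filter(function(h) {
    left <- exists(key(h$i - 1, h$j, h$L + 1), envir = all_pairs)
    right <- exists(key(h$i, h$j - 1, h$L + 1), envir = all_pairs)
    h$L >= min_len && !left && !right
  }, hits)
  if (!length(keep))
    return(data.frame(match1 = character(0), match2 = character(0),
                      length = integer(0), start1 = integer(0), start2 = integer(0)))
  df <- do.call(rbind, lapply(keep, function(h)
    data.frame(match1 = substr(s1, h$i, h$i + h$L - 1),
               match2 = substr(s2, h$j, h$j + h$L - 1),
               length = h$L, start1 = h$i, start2 = h$j,
               stringsAsFactors = FALSE)))
  df[order(-df$length, df$start1, df$start2), , drop = FALSE]
}

# tiny deterministic gene model used across tests: 12-bp sequence,
# exons (1-4) and (9-12), cDNA = AAAC + GTTT
toy_model <- function() {
  splicesleuth::gene_model("toy", "AAACGGGAGTTT",
                           data.frame(start = c(1L, 9L), end = c(4L, 12L)))
}
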