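# Independent oracles: deliberately naive implementations that never share
# code paths with the package internals they check.

rnd_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_hamming <- function(x, y) {
  sum(mapply(function(a, b) a != b,
             strsplit(x, "")[[1]], strsplit(y, "")[[1]]))
}

oracle_gap_cost <- function(k, params) {
  if (k == 0L) 0 else params$gap_open + (k - 1L) * params$gap_extend
}

# Exhaustive global alignment score by enumerating every chain of aligned
# column pairs; the residues between consecutive aligned columns are costed
# as one gap run per sequence (provably optimal arrangement given
# gap_open <= gap_extend <= 0). Exponential on purpose.
oracle_global_score <- function(a, b, params) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  sc <- function(x, y) {
    if (x == "N" || y == "N" || x != y) params$mismatch else params$match
  }
  rec <- function(i, j) {
    best <- oracle_gap_cost(n - i, params) + oracle_gap_cost(m - j, params)
    if (i < n && j < m) {
      for (i2 in (i + 1L):n) {
        for (j2 in (j + 1L):m) {
          v <- oracle_gap_cost(i2 - i - 1L, params) +
            oracle_gap_cost(j2 - j - 1L, params) +
            sc(av[i2], bv[j2]) + rec(i2, j2)
          if (v > best) best <- v
        }
      }
    }
    best
  }
  rec(0L, 0L)
}

# Local score = best global score over all substring pairs, floored at 0,
# where end gaps never help (so plain global on the substrings is right).
oracle_local_score <- function(a, b, params) {
  n <- nchar(a); m <- nchar(b)
  best <- 0
  for (i1 in 1:n) for (i2 in i1:n) for (j1 in 1:m) for (j2 in j1:m) {
    v <- oracle_global_score(substr(a, i1, i2), substr(b, j1, j2), params)
    if (v > best) best <- v
  }
  best
}

# exact-match RSS scan (mismatch 0) by direct window comparison
oracle_scan_rss0 <- function(res, motif) {
  n <- nchar(res)
  if (n < 28L) return(integer(0))
  out <- integer(0)
  for (p in 0:(n - 28L)) {
    if (motif$side == "three_prime") {
      ok <- substr(res, p + 1, p + 7) == motif$heptamer &&
        substr(res, p + 20, p + 28) == motif$nonamer
    } else {
      ok <- substr(res, p + 1, p + 9) == motif$nonamer &&
        substr(res, p + 22, p + 28) == motif$heptamer
    }
    if (ok) out <- c(out, p)
  }
  out
}

oracle_min_rotation <- function(u) {
  n <- nchar(u)
  doubled <- paste0(u, u)
  sort(vapply(1:n, function(k) substr(doubled, k, k + n - 1L), ""))[1]
}

# primitive = not a whole-number power of a shorter unit
is_primitive_unit <- function(u) {
  L <- nchar(u)
  for (d in seq_len(L - 1L)) {
    if (L %% d == 0L && strrep(substr(u, 1, d), L %/% d) == u) return(FALSE)
  }
  TRUE
}

rand_primitive_unit <- function(L) {
  repeat {
    u <- rnd_dna(L)
    if (is_primitive_unit(u)) return(u)
  }
}

# plant unit^n between flanks whose boundary characters cannot extend the
# array (so the planted copy number is exactly recoverable)
plant_array <- function(unit, n_copies, flank = 8L) {
  L <- nchar(unit)
  fl <- rnd_dna(flank); fr <- rnd_dna(flank)
  last <- substr(unit, L, L); first <- substr(unit, 1, 1)
  if (substr(fl, flank, flank) == last)
    substr(fl, flank, flank) <- setdiff(c("A", "C", "G", "T"), last)[1]
  if (substr(fr, 1, 1) == first)
    substr(fr, 1, 1) <- setdiff(c("A", "C", "G", "T"), first)[1]
  list(seq = paste0(fl, strrep(unit, n_copies), fr),
       array_start = flank, array_end = flank + n_copies * L)
}
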