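# Independent oracles used by the tests. These deliberately re-derive
# results by brute force or closed form, never by calling the code paths
# they check.

# literal five-deep enumeration over small element bounds
brute_match_formula <- function(measured_mz, adduct, bounds, tol_ppm) {
  rows <- list()
  for (c_ in bounds$C[1]:bounds$C[2])
    for (h in bounds$H[1]:bounds$H[2])
      for (n in bounds$N[1]:bounds$N[2])
        for (o in bounds$O[1]:bounds$O[2])
          for (s in bounds$S[1]:bounds$S[2]) {
            if (c_ + h + n + o + s < 1) next
            cnt <- c(C = c_, H = h, N = n, O = o, S = s)
            theo <- adduct_mz(cnt[cnt > 0], adduct)
            ppm <- (measured_mz - theo) / theo * 1e6
            r <- c_ - h / 2 + n / 2 + 1
            if (abs(ppm) <= tol_ppm && r >= 0 && r <= 40) {
              rows[[length(rows) + 1L]] <-
                data.frame(C = c_, H = h, N = n, O = o, S = s, ppm = ppm)
            }
          }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  out[order(abs(out$ppm)), , drop = FALSE]
}

# textbook Pearson r from sums, no cor()
hand_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# average-linkage agglomeration traced by hand from a distance matrix;
# returns merge heights and the member sets merged at each step
brute_average_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  sets <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    sets[[length(sets) + 1L]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  list(heights = heights, sets = sets)
}

# member sets merged at each hclust step, for comparison with the oracle
hclust_merge_sets <- function(merge) {
  n <- nrow(merge) + 1L
  members <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    grab <- function(idx) if (idx < 0) -idx else members[[idx]]
    members[[k]] <- sort(c(grab(merge[k, 1]), grab(merge[k, 2])))
  }
  members
}

# reference [M-H]- exactness set: formula -> reported value (4 dp or as reported)
reference_mh_printed <- c(
  C7H6O4    = 153.0193,
  C32H36O16 = 675.1931,
  C16H16O8  = 335.0772,
  C18H26O8  = 369.1555,
  C21H20O12 = 463.0882,
  C27H30O16 = 609.1461,
  C33H48O16 = 699.287,
  C21H20O11 = 447.0933,
  C28H32O13 = 575.177,
  C30H26O14 = 609.125,
  C20H36O12 = 467.2134,
  C28H46O8  = 509.312
)

reference_formulas <- c("C7H6O4", "C16H18O9", "C32H36O16", "C16H16O8",
                     "C18H26O8", "C21H20O12", "C27H30O16", "C33H48O16",
                     "C21H20O11", "C28H32O13", "C30H26O14", "C20H36O12",
                     "C22H38O12", "C28H46O8")
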