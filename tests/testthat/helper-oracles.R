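# Independent oracles used across the suite. They deliberately avoid the
# package's formula/enumeration code paths.

# monoisotopic mass of a formula string like "C17H33O2", computed with an
# independently transcribed mass table and a simple token scan
oracle_mass <- function(formula, charge = 0) {
  masses <- c(C = 12, H = 1.00782503, D = 2.01410178, N = 14.00307400,
              O = 15.99491462, P = 30.97376163)
  toks <- regmatches(formula,
                     gregexpr("[A-Z][0-9]*", formula))[[1]]
  m <- 0
  for (tk in toks) {
    el <- substr(tk, 1, 1)
    n <- if (nchar(tk) > 1) as.numeric(substr(tk, 2, nchar(tk))) else 1
    m <- m + n * masses[[el]]
  }
  if (charge == 0) return(m)
  (m - charge * 0.000548579909) / abs(charge)
}

# brute-force TG composition enumeration over pool^3 with deduplication
oracle_enumerate <- function(total_c, total_db, pool_str) {
  parse1 <- function(s) as.numeric(strsplit(s, ":")[[1]])
  fas <- lapply(pool_str, parse1)
  seen <- character(0)
  for (a in fas) for (b in fas) for (c in fas) {
    if (a[1] + b[1] + c[1] == total_c && a[2] + b[2] + c[2] == total_db) {
      trip <- sort(vapply(list(a, b, c),
                          function(f) sprintf("%02d:%02d", f[1], f[2]),
                          character(1)))
      key <- paste(sub("^0", "", sub(":0(\\d)$", ":\\1", trip)),
                   collapse = "_")
      seen <- union(seen, key)
    }
  }
  sort(seen)
}

# all-pairs single-linkage clustering of apex times: merge clusters while
# any two points in different clusters are within tol
oracle_cluster <- function(rts, tol) {
  n <- length(rts)
  lab <- seq_len(n)
  repeat {
    merged <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (lab[i] != lab[j] && abs(rts[i] - rts[j]) <= tol) {
        lab[lab == lab[j]] <- lab[i]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  match(lab, unique(lab))
}

# canonicalize enumeration output of the package for comparison
pkg_enumerate <- function(total_c, total_db, pool_str) {
  pool <- lapply(pool_str, parse_fa)
  sort(vapply(enumerate_tg_compositions(total_c, total_db, pool),
              composition_string, character(1)))
}

# a synthetic trace with Gaussian peaks at given rts/heights
make_trace <- function(rts, heights, width = 0.08, from = 0, to = 30,
                       step = 0.02, id = "t", fa = NA_character_,
                       noise_sd = 0, seed = 1) {
  grid <- seq(from, to, by = step)
  y <- numeric(length(grid))
  for (k in seq_along(rts)) {
    y <- y + heights[k] * exp(-0.5 * ((grid - rts[k]) / width)^2)
  }
  if (noise_sd > 0) {
    # noisy traces ride on a baseline offset, as real MRM data do; keeps
    # the zero-clamp from biasing noise estimation
    set.seed(seed)
    y <- pmax(y + 4 * noise_sd + rnorm(length(y), 0, noise_sd), 0)
  }
  structure(list(id = id, precursor = NA_character_, channel = NA_character_,
                 fa = fa, is_standard = FALSE, rt = grid, intensity = y),
            class = "xic_trace")
}
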