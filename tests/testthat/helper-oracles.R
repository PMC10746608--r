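# Independent oracles and small builders shared across tests. The oracles
# deliberately avoid the code paths they check: the tail oracle sums the
# hypergeometric pmf from log-binomial coefficients, and the BH oracle is a
# literal transcription of the step-up procedure.

# P(X >= k), X ~ Hypergeometric(N, K, n), by pmf summation over the support.
oracle_tail <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  x <- k:hi
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

# Full pmf of X ~ Hypergeometric(N, K, n) over its support lo..hi.
oracle_pmf <- function(K, n, N) {
  lo <- max(0L, n + K - N); hi <- min(K, n)
  x <- lo:hi
  list(x = x, p = exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

# Literal BH step-up: sort ascending, q_i = p_(i) m / i, enforce
# monotonicity from the largest rank down, cap at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# A tiny library built directly from member vectors.
make_library <- function(members_list, library_id = "toy",
                         background_size = 1000L, tf_names = NULL,
                         background_universe = NULL) {
  sets <- lapply(seq_along(members_list), function(i) {
    nm <- names(members_list)[i]
    list(name = nm, description = "",
         members = coreTF::normalize_symbols(members_list[[i]]),
         tf_symbol = if (is.null(tf_names)) NULL else tf_names[i])
  })
  coreTF::gene_set_library(sets, library_id, background_size,
                           background_universe)
}

extdata <- function(...) {
  system.file("extdata", ..., package = "coreTF", mustWork = TRUE)
}
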