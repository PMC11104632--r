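# Independent oracles used across tests. Each reimplements the checked
# operation by a different route than the package code.

# --- 32-bit xorshift oracle in pure R (16-bit halves, no C code) ---------

xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}

oracle_xorshift32 <- function(x) {
  x <- xor32(x, (x * 2^13) %% 2^32)   # x ^= x << 13
  x <- xor32(x, x %/% 2^17)           # x ^= x >> 17
  x <- xor32(x, (x * 2^5) %% 2^32)    # x ^= x << 5
  x
}

oracle_xorshift_seq <- function(seed, n) {
  out <- numeric(n)
  x <- seed
  for (i in seq_len(n)) {
    x <- oracle_xorshift32(x)
    out[i] <- x
  }
  out
}

# --- cluster oracle: transitive closure over the point adjacency ---------

oracle_qualifying_hemifields <- function(pd, layout = vf_layout()) {
  rank <- match(pd, pd_categories())
  flags <- c(superior = FALSE, inferior = FALSE)
  clusters <- list()
  for (hemi in c("superior", "inferior")) {
    sel <- which(rank >= 2 & !layout$is_blind_spot &
                   (if (hemi == "superior") layout$y > 0 else layout$y < 0))
    if (length(sel) == 0) next
    n <- length(sel)
    adj <- outer(layout$x[sel], layout$x[sel],
                 function(a, b) abs(a - b) <= 6) &
      outer(layout$y[sel], layout$y[sel], function(a, b) abs(a - b) <= 6)
    diag(adj) <- TRUE
    reach <- adj
    repeat {
      nxt <- (reach %*% reach) > 0
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    comp_id <- apply(reach, 1, function(r) min(which(r)))
    for (cid in unique(comp_id)) {
      members <- sel[comp_id == cid]
      counted <- sum(!layout$is_edge[members]) +
        min(2, sum(layout$is_nasal_edge[members]))
      if (counted >= 3 && any(rank[members] >= 4)) {
        flags[[hemi]] <- TRUE
        clusters[[length(clusters) + 1]] <- sort(members)
      }
    }
  }
  list(flags = flags, clusters = clusters)
}

random_pd_map <- function(p_abnormal = 0.15) {
  pd <- sample(pd_categories(), 76, replace = TRUE,
               prob = c(1 - p_abnormal, p_abnormal * c(0.4, 0.25, 0.2, 0.15)))
  pd
}

# --- agreement truth table (hand enumerated) -----------------------------

# columns: vf superior/inferior flags, shadow responded, shadow hemifield
# flags; expected category per the hemifield-coincidence definitions.
agreement_truth_table <- function() {
  rows <- list(
    list(c(TRUE, FALSE), TRUE, c(TRUE, FALSE), "Agreement"),
    list(c(TRUE, FALSE), TRUE, c(FALSE, TRUE), "NoAgreement"),
    list(c(TRUE, FALSE), TRUE, c(TRUE, TRUE), "PartialAgreement"),
    list(c(FALSE, TRUE), TRUE, c(TRUE, FALSE), "NoAgreement"),
    list(c(FALSE, TRUE), TRUE, c(FALSE, TRUE), "Agreement"),
    list(c(FALSE, TRUE), TRUE, c(TRUE, TRUE), "PartialAgreement"),
    list(c(TRUE, TRUE), TRUE, c(TRUE, FALSE), "PartialAgreement"),
    list(c(TRUE, TRUE), TRUE, c(FALSE, TRUE), "PartialAgreement"),
    list(c(TRUE, TRUE), TRUE, c(TRUE, TRUE), "Agreement"),
    list(c(TRUE, FALSE), FALSE, c(FALSE, FALSE), "NoResponse"),
    list(c(FALSE, TRUE), FALSE, c(FALSE, FALSE), "NoResponse"),
    list(c(TRUE, TRUE), FALSE, c(FALSE, FALSE), "NoResponse")
  )
  rows
}

shadow_from_flags <- function(responded, flags) {
  regions <- list()
  if (flags[1]) regions <- c(regions, list(shadow_region("sup_nasal", 10)))
  if (flags[2]) regions <- c(regions, list(shadow_region("inf_temporal", 12)))
  shadow_record(responded = responded, reproducible = responded,
                regions = regions)
}

# strip noise_frame attributes for raw-matrix comparisons
bare <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# --- small rendering shortcut --------------------------------------------

small_config <- function(algorithm = "xorshift32", seed = 1, width = 70,
                         height = 49, dot = 7, n_frames = 4,
                         palette = gray_palette()) {
  stimulus_config(width_px = width, height_px = height, dot_px = dot,
                  palette = palette, n_frames = n_frames,
                  rng = rng_state(algorithm, seed))
}
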