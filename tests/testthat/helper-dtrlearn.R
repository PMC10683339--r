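# Deterministic noiseless trial: y = 1 + 2*z1 + a2*(3 - z1), everyone
# re-randomized. The stage-2 model with main = effect = z1 is saturated
# and exact, so fits recover (1, 2) and (3, -1) with zero residuals.
noiseless_trial <- function(n = 12) {
  z1 <- seq(-2, 2, length.out = n)
  a1 <- rep(c(-1, 1), length.out = n)
  a2 <- rep(c(-1, -1, 1, 1), length.out = n)
  tibble::tibble(
    id = seq_len(n), z1 = z1, a1 = a1, z2 = round(cos(3 * seq_len(n)), 3),
    rerandomized = TRUE, a2 = a2,
    y = 1 + 2 * z1 + a2 * (3 - z1)
  )
}

# Mixed embedded-tailoring variant: even subjects are not re-randomized and
# keep the stage-1-only outcome; arm patterns vary within the re-randomized
# subset so every design block stays full rank.
tailored_trial <- function(n = 16) {
  z1 <- seq(-2, 2, length.out = n)
  rer <- seq_len(n) %% 2L == 1L
  a1 <- rep(c(-1, 1, 1, -1), length.out = n)
  a2 <- rep(c(-1, -1, 1, 1), length.out = n)
  a2[!rer] <- NA
  y <- 1 + 2 * z1
  y[rer] <- y[rer] + a2[rer] * (3 - z1[rer])
  tibble::tibble(
    id = seq_len(n), z1 = z1, a1 = a1,
    z2 = round(cos(3 * seq_len(n)), 3),
    rerandomized = rer, a2 = a2, y = y
  )
}

spec1_z1 <- function() model_spec(1, main = "z1", effect = "z1")
spec2_z1 <- function() model_spec(2, main = "z1", effect = "z1")
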