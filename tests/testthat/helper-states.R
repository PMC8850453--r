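# Shared helpers: random in-arena states and a percentile bootstrap CI.

random_states <- function(n, seed, arena = pedvortex::arena(),
                          speed_range = c(0.2, 2.5), with_chirality = TRUE) {
  set.seed(seed)
  pos <- cbind(runif(n, -arena$width / 2 + 0.3, arena$width / 2 - 0.3),
               runif(n, -arena$height / 2 + 0.3, arena$height / 2 - 0.3))
  th <- runif(n, 0, 2 * pi)
  head <- cbind(cos(th), sin(th))
  sp <- runif(n, speed_range[1], speed_range[2])
  list(positions = pos, velocities = sp * head, headings = head,
       chiralities = if (with_chirality) sample(c(-1L, 1L), n, TRUE)
                     else rep(NA_integer_, n))
}

boot_ci_mean <- function(x, B = 2000, level = 0.95, seed = 42) {
  set.seed(seed)
  means <- replicate(B, mean(sample(x, replace = TRUE)))
  unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}
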