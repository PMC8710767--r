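# shared fixtures, built in code at test time

tinyConfig <- function(seed = 7L, ...) {
  args <- list(grid_side = 32, n_participants = 8, noise_sd = 0.02,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(phantomConfig, args)
}

tinyNet <- function(seed = 3L) buildNetwork(unetSpec(base_channels = 2), seed)

# a random blob mask of the given grid side (always nonempty)
randomMask <- function(g, seed) {
  set.seed(seed)
  ctr <- runif(3, 0.3 * g, 0.7 * g)
  rad <- runif(1, 0.15 * g, 0.35 * g)
  co <- seq_len(g)
  d2 <- outer(outer((co - ctr[1])^2, (co - ctr[2])^2, "+"), (co - ctr[3])^2, "+")
  m <- d2 <= rad^2
  if (!any(m)) m[ceiling(g / 2), ceiling(g / 2), ceiling(g / 2)] <- TRUE
  m
}

# memoised desk-scale end-to-end experiment shared by the acceptance tests
.fixtureEnv <- new.env(parent = emptyenv())
deskFixture <- function() {
  if (is.null(.fixtureEnv$res))
    .fixtureEnv$res <- runPipeline(deskConfig(seed = 1))
  .fixtureEnv$res
}
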