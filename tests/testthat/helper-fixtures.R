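# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# training faces (odd identities) and their bank: 6 images x 10 templates
tiny_train <- function() fixture("tiny_train", function()
  render_identity_set(seq(1, 11, 2), seed = 42))

tiny_bank <- function() fixture("tiny_bank", function()
  learn_bank(tiny_train(), per_image = 10, seed = 99))

# test faces (even identities)
tiny_test <- function(n = 6) fixture(paste0("tiny_test", n), function()
  render_identity_set(seq(2, 2 * n, 2), seed = 42))

tiny_c1 <- function() fixture("tiny_c1", function()
  c1_layer(s1_layer(build_pyramid(tiny_test()[[1]]))))

# small random C1-like stack for layer oracles
random_s1 <- function(scales, n_or = 4, seed = 1) {
  with_local_seed_test(seed, lapply(scales, function(n)
    array(stats::runif(n * n * n_or), c(n, n, n_or))))
}

with_local_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
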