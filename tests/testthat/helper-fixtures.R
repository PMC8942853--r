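# Shared fixtures, generated once per test run (all code, no stored data).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

test_config <- function() synthetic_config(seed = 42, n_species = 6,
                                           specimens_per_species = 1)

test_specimen <- function() {
  fixture("specimen", function() generate_specimen(test_config(), 3))
}

test_hull <- function() {
  fixture("hull", function() generate_rom_hull(test_config(), 3))
}

test_sweep <- function() {
  fixture("sweep", function() {
    g <- test_specimen()
    sweep_rom(g$morphology, g$feathers, test_hull(), grid_step = 15)
  })
}

test_tree_traits_ou <- function() {
  fixture("ttou", function() {
    generate_tree_and_traits(synthetic_config(seed = 7, n_species = 22),
                             model = "OU",
                             params = c(alpha = 3, sigma2 = 1, theta = 0.5))
  })
}
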