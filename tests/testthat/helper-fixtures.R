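## Session-cached fixtures: meshes and reference sets are expensive enough
## that each is built once per test run and shared across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## Coarse disk (h = 0.6): fast unit-test workhorse.
disk_coarse <- function() fixture("disk_coarse", function() {
  dom <- make_domain("disk", radius = 10)
  el <- place_electrodes(dom, 10L, width = 2, arc_span = 1)
  mesh <- build_mesh(dom, el, h = 0.6)
  layers <- compute_layers(mesh, d0 = 0.3, L = 15L)
  protocol <- make_protocol(10L, current = 1)
  list(dom = dom, el = el, mesh = mesh, layers = layers, protocol = protocol)
})

disk_coarse_ref <- function() fixture("disk_coarse_ref", function() {
  d <- disk_coarse()
  reference_set(d$mesh, d$protocol)
})

## Small protocol for combinatorial tests.
proto5 <- function() fixture("proto5", function() make_protocol(5L, 1))

## A tiny trained MLP on a miniature corpus (small net, coarse disk):
## used by reconstruction-path tests that need a plausible fitted model
## without the full training cost.
tiny_model_kit <- function() fixture("tiny_model_kit", function() {
  d <- disk_coarse()
  ref <- disk_coarse_ref()
  parts <- expand.grid(l_f = c(2L, 4L, 6L, 8L), l_m = c(10L, 14L))
  conds <- data.frame(gamma_f = 1, gamma_m = c(4, 8), gamma_r = c(2.5, 5.5))
  specs <- merge(parts, conds, by = NULL)
  ds <- generate_dataset(d$mesh, d$layers, d$protocol, specs, ref = ref)
  ## tiny corpus: full-batch Adam needs many more (cheap) steps
  model <- eit_mlp(ds, hidden = c(64L, 32L), epochs = 3000L,
                   batch_size = 16L, lr = 3e-3, lr_halve_every = 1000L,
                   validation_split = 0, target_rmse = 0.05,
                   restart_rmse = 0.3, seed = 42L)
  list(kit = d, ref = ref, ds = ds, specs = specs, model = model)
})
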