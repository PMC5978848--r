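# Shared fixtures, built once per test run and memoized.
# The "coarse" study setup (486 heart nodes, 5 mm wall sampling) backs most
# pipeline tests; the "default" setup (1446 heart nodes, 3 mm sampling) is the
# study-scale geometry used by the acceptance tests that need it.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

coarse_config <- function() {
  study_config(list(geometry = list(
    axes = c(38, 35, 55), wall_thickness = 11,
    subdiv = c(epi = 2, lv = 2, rv = 2),
    grid_spacing = 5, fiber_rotation = 120,
    torso_subdiv = 3, lung_subdiv = 2, n_electrodes = 120)))
}

coarse_setup <- function() fixture("coarse_setup", function() {
  study_setup(coarse_config())
})

default_setup <- function() fixture("default_setup", function() {
  study_setup(study_config())
})

unit_sphere <- function(subdiv = 2) {
  ellipsoid_surface(c(1, 1, 1), subdiv = subdiv, label = "sphere")
}

sphere_solver <- function(subdiv = 2, sigma = 1) {
  key <- sprintf("sphere_solver_%d_%g", subdiv, sigma)
  fixture(key, function() {
    s <- unit_sphere(subdiv)
    vcm <- volume_conductor(list(sphere = list(surface = s, sigma_in = sigma,
                                               sigma_out = 0)),
                            electrodes = seq_len(50), check = FALSE)
    attr(vcm, "sigma_heart") <- sigma
    list(surface = s, solver = assemble_bem(vcm))
  })
}

# single-chamber ventricle, cheap variant for unit tests
single_ventricle <- function() fixture("single_ventricle", function() {
  build_ventricle(axes = c(30, 30, 45), wall_thickness = 10,
                  subdiv = c(epi = 2, lv = 2), grid_spacing = 4,
                  chambers = "single")
})
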