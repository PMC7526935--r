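# Small-scale geometry/scan shared by the slower pipeline tests; fine enough
# for the rebinning and reconstruction tolerances asserted, small enough to
# keep the suite fast.
test_geometry <- function(n_channels = 368, views_per_rotation = 360)
  system_geometry(n_channels = n_channels,
                  views_per_rotation = views_per_rotation)

test_grid <- function(n = 128) recon_grid(n, 250 / n)

# cache expensive objects across tests within one run
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .test_cache)) assign(key, force(expr), .test_cache)
  get(key, .test_cache)
}

static_scan <- function() cached("static_scan", {
  geo <- test_geometry()
  forward_project(preset_phantom("static"), geo, scan_timeline(geo, 2))
})

# single off-centre disk phantom (static), handy analytic case
disk_phantom <- function(r = 20, mu = 0.04, center = c(30, -10)) {
  dynamic_phantom(list(
    tv_primitive("disk", "ellipse", mu, center, c(r, r))),
    ecg_model(60), fov_extent = 2 * (sqrt(sum(center^2)) + r) + 2)
}
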