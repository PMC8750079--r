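# Shared fixtures: range models and a uniform dose grid builder.

rm_tab <- range_model("tabulated")
rm_pow <- range_model()

uniform_dose_grid <- function(value = 1) {
  x <- seq(-20, 20, by = 0.5)
  y <- seq(-10, 10, by = 5)
  z <- seq(1, 99, by = 2)
  dose_grid(array(value, c(length(x), length(y), length(z))), x, y, z)
}

# memoised store for expensive end-to-end grids shared across test files
.e2e_cache <- new.env(parent = emptyenv())

e2e_grids_150 <- function() {
  if (!is.null(.e2e_cache$grids)) return(.e2e_cache$grids)
  s1 <- make_scenario("config1")
  s3p <- make_scenario("config3p")
  ft3 <- build_field_table(s3p, 150, rm_tab)
  .e2e_cache$grids <- list(
    ft3 = ft3,
    d1 = compute_dose(s1, 150, model = rm_tab),
    d3p = compute_dose(s3p, 150, ft3, model = rm_tab))
  .e2e_cache$grids
}
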