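# Lazily-built fixtures shared across test files (built once per run).
.fix_env <- new.env()
fixture <- function(name, expr) {
  if (!exists(name, envir = .fix_env, inherits = FALSE))
    assign(name, expr, envir = .fix_env)
  get(name, envir = .fix_env, inherits = FALSE)
}

cohort29 <- function() fixture("cohort29", generate_training_cohort(seed = 101))

records29 <- function() fixture(
  "records29", samples_from_cohort(cohort29(), seed = 102))

# one mid-range IRD retina with comfortably separated bands
retina_mid <- function() fixture("retina_mid", {
  co <- cohort29()
  ok <- co$gt_cos_fovea > 12 & co$gt_onl_fovea > 60 & co$gt_onl_fovea < 120
  ground_truth_retina(co[which(ok)[1], ])
})

scan_clean <- function() fixture(
  "scan_clean",
  render_bscan(retina_mid(), lateral_extent = 3, n_ascans = 256,
               noise_sd = 0, seed = 7))

# hand-built bscan for toy tests
toy_bscan <- function(refl, depth = seq(0, by = 2,
                                        length.out = nrow(refl)),
                      lateral = seq(-1, 1, length.out = ncol(refl)),
                      aligned = TRUE) {
  structure(list(reflectivity = refl, depth_um = depth, lateral_deg = lateral,
                 aligned = aligned, foveola = NA_real_), class = "bscan")
}
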