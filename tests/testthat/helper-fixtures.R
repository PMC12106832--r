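# Shared fixtures built in code.

feature_set <- c("gyrification_index",
                 paste0(c("eCSF", "cGM", "WM", "dGM", "lateral_ventricles",
                          "cerebellum", "brainstem", "hippocampus"), "_mm3"),
                 "csf_mm3", "icv_mm3")

volume_features <- setdiff(feature_set, "gyrification_index")

# minimal hand-written cohort rows
tiny_cohort <- function(n = 3) {
  data.frame(
    session_id = paste0("s", seq_len(n)),
    participant_id = paste0("p", seq_len(n)),
    cohort = "marsfet", group = "fetal",
    scan_age_wpc = seq(25, 30, length.out = n),
    birth_age_wpc = NA_real_,
    sex = rep(c("M", "F", "NA"), length.out = n),
    scanner_id = "sc1", field_strength_tesla = 3.0,
    gyrification_index = seq(1.1, 1.3, length.out = n),
    stringsAsFactors = FALSE)
}

normative_table <- function(seed, params = trajectory_params(), ...)
  filter_group(simulate_cohort(simulation_config(...), params, seed = seed),
               c("fetal", "postnatal"))

# deterministic proper rotation + translation
random_rigid_motion <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 10))
}

apply_rigid <- function(m, motion)
  mesh(sweep(m$vertices %*% t(motion$R), 2, motion$t, `+`), m$faces)

# piecewise-quadratic outcome with a sharp jump J at the cutoff
piecewise_quadratic <- function(ages, cutoff, J,
                                coefs = c(0.2, 0.03, 0.002)) {
  x <- ages - cutoff
  coefs[1] + coefs[2] * x + coefs[3] * x^2 + J * (ages >= cutoff)
}

# age design echoing the bimodal fetal/postnatal sampling
bimodal_ages <- function(n_left = 180, n_right = 220) {
  c(seq(22, 36.9, length.out = n_left), seq(37.4, 44.9, length.out = n_right))
}
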