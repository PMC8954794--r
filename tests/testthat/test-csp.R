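mk_table <- function(dH, dN, ratio = 1, site = NULL, residue = NULL) {
  n <- length(dH)
  if (is.null(residue)) residue <- seq_len(n)
  if (is.null(site)) site <- rep("backbone_NH", n)
  shift_table(data.frame(residue = residue, site = site,
                         delta_H_ppm = dH, delta_N_ppm = dN),
              ratio = ratio)
}

test_that("combined CSP follows the scaled quadrature formula", {
  apo <- mk_table(rep(8, 3), rep(115, 3))
  bound <- mk_table(c(8, 8.03, 8.05), c(115 + 5.88, 115, 115.3))
  v <- compute_csp(apo, bound)$data
  expect_equal(v$csp_ppm[1], 1.000, tolerance = 1e-12)      # dN = 5.88 alone
  expect_equal(v$csp_ppm[2], 0.030, tolerance = 1e-12)      # dH alone
  expect_equal(v$csp_ppm[3], sqrt((0.3 / 5.88)^2 + 0.05^2),
               tolerance = 1e-12)                            # 0.0714 ppm
})

test_that("CSP is zero iff both differences are zero, symmetric, and offset-invariant", {
  set.seed(7)
  n <- 30
  apo <- mk_table(runif(n, 6, 10), runif(n, 105, 130))
  b <- apo$data
  b$delta_H_ppm <- b$delta_H_ppm + c(rep(0, 10), rnorm(20, 0, 0.05))
  b$delta_N_ppm <- b$delta_N_ppm + c(rep(0, 10), rnorm(20, 0, 0.3))
  bound <- shift_table(b, ratio = 1)

  fwd <- compute_csp(apo, bound)$data
  rev <- compute_csp(bound, apo)$data
  expect_equal(fwd$csp_ppm, rev$csp_ppm)
  expect_true(all((fwd$csp_ppm == 0) == (fwd$delta_H == 0 & fwd$delta_N == 0)))
  expect_true(all(fwd$csp_ppm[1:10] == 0))

  # a uniform additive offset on both tables changes nothing
  shift_all <- function(tb, dh, dn) {
    d <- tb$data
    d$delta_H_ppm <- d$delta_H_ppm + dh
    d$delta_N_ppm <- d$delta_N_ppm + dn
    shift_table(d, ratio = tb$ratio)
  }
  off <- compute_csp(shift_all(apo, 0.3, -2), shift_all(bound, 0.3, -2))$data
  expect_equal(off$csp_ppm, fwd$csp_ppm)

  # classification is invariant to site ordering
  perm <- sample(n)
  bound_perm <- shift_table(bound$data[perm, ], ratio = 1)
  c1 <- classify_csp(compute_csp(apo, bound))
  c2 <- classify_csp(compute_csp(apo, bound_perm))
  expect_equal(c1$data$class, c2$data$class)
  expect_equal(c1$threshold_2sd, c2$threshold_2sd)
})

test_that("SD classification separates planted binding sites from background", {
  # uniform CSPs: zero SD, everything below threshold
  apo <- mk_table(rep(8, 10), rep(115, 10))
  bshift <- mk_table(rep(8.05, 10), rep(115, 10))
  cls <- classify_csp(compute_csp(apo, bshift))
  expect_equal(cls$sd_ppm, 0)
  expect_true(all(cls$data$class == "below"))

  # default synthetic titration: recovered site set equals the planted one
  truth <- ground_truth()
  tabs <- sim_titration_tables(truth, cfg = sim_config(seed = 5))
  prof <- classify_csp(compute_csp(tabs[[1]], tabs[[length(tabs)]]))
  hits <- prof$data[prof$data$class != "below", c("residue", "site")]
  expect_setequal(paste(hits$residue, hits$site),
                  paste(truth$binding_site$residue, truth$binding_site$site))

  expect_error(classify_csp(compute_csp(mk_table(rep(8, 4), rep(115, 4)),
                                        mk_table(rep(8.1, 4), rep(115, 4)))),
               "at least 5")
})

test_that("unmatched sites are reported, never silently dropped", {
  apo <- mk_table(rep(8, 6), rep(115, 6), residue = 1:6)
  bound <- mk_table(rep(8.02, 5), rep(115.1, 5), residue = 2:6)
  v <- compute_csp(apo, bound)
  expect_equal(nrow(v$data), 5)
  expect_equal(v$unmatched$residue, 1)
  expect_equal(v$unmatched$missing_in, "bound")
  expect_error(compute_csp(mk_table(8, 115, residue = 1),
                           mk_table(8, 115, residue = 2)), "no shared")
})

test_that("titration trajectories are flat for identical tables and track the binding quadratic", {
  apo <- mk_table(rep(8, 8), rep(115, 8), ratio = 0)
  same <- mk_table(rep(8, 8), rep(115, 8), ratio = 1)
  tj <- titration_trajectory(list(apo, same))
  expect_true(all(tj$trajectory$csp_ppm == 0))

  # noiseless tight-binding titration saturates at the full amplitude
  truth <- ground_truth()
  truth$itc$Kd_M <- 1e-12
  tabs <- sim_titration_tables(truth, ratios = c(0, 0.5, 1, 2),
                               cfg = sim_config(seed = 9, noise_sd = 0),
                               noise_H_ppm = 0, noise_N_ppm = 0)
  endpoint <- compute_csp(tabs[[1]], tabs[[4]])$data
  key <- paste(endpoint$residue, endpoint$site)
  skey <- paste(truth$binding_site$residue, truth$binding_site$site)
  got <- endpoint$csp_ppm[match(skey, key)]
  expect_equal(got, truth$binding_site$amplitude, tolerance = 1e-6)

  # finite-affinity endpoint equals amplitude x quadratic-root saturation
  truth2 <- ground_truth()
  P <- 500e-6
  tabs2 <- sim_titration_tables(truth2, ratios = c(0, 2),
                                cfg = sim_config(seed = 9, noise_sd = 0),
                                protein_M = P,
                                noise_H_ppm = 0, noise_N_ppm = 0)
  f_oracle <- local({
    L <- 2 * P; Kd <- truth2$itc$Kd_M
    b <- P + L + Kd
    (b - sqrt(b^2 - 4 * P * L)) / (2 * P)
  })
  ep2 <- compute_csp(tabs2[[1]], tabs2[[2]])$data
  key2 <- paste(ep2$residue, ep2$site)
  got2 <- ep2$csp_ppm[match(skey, key2)]
  expect_equal(got2, truth2$binding_site$amplitude * f_oracle,
               tolerance = 1e-9)

  expect_error(titration_trajectory(list(same, apo)), "ratio 0")
})

test_that("CSP-to-structure mapping writes the scaled B-factor and round-trips", {
  truth <- ground_truth()
  ens <- sim_ensemble(reference_model(40), n_models = 2, dispersion = 0.5,
                      cfg = sim_config(seed = 2))
  apo <- mk_table(rep(8, 40), rep(115, 40))
  b <- apo$data
  b$delta_H_ppm[5] <- b$delta_H_ppm[5] + 0.30    # 0.30 ppm CSP at residue 5
  prof <- classify_csp(compute_csp(apo, shift_table(b, ratio = 2)))
  out <- file.path(tempdir(), "csp_map.pdb")
  map_csp_to_structure(prof, ens, out)
  back <- bio3d::read.pdb(out, verbose = FALSE)
  expect_equal(unique(back$atom$b[back$atom$resno == 5]), 30.00,
               tolerance = 1e-9)
  expect_equal(unique(back$atom$b[back$atom$resno == 6]), 0)
  side <- read.delim(paste0(out, ".classes.tsv"))
  expect_equal(side$csp_ppm[side$residue == 5], 0.30, tolerance = 1e-12)

  empty <- prof
  empty$data <- prof$data[0, ]
  expect_error(map_csp_to_structure(empty, ens, out), "no backbone sites")
})
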