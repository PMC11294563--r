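#!/usr/bin/env Rscript
# Kinetics of redistribution at symmetry breaking: the memory/responsiveness
# tradeoff. The system starts equilibrated with no plasma-membrane
# preference (kd_mem = 1, protein on internal membranes and cytoplasm);
# at t = 0 the plasma membrane becomes available (kd_mem drops to the
# fitted value) and the three-compartment exchange ODEs relax toward the
# new equilibrium. Strong dimerization gives the best final PM occupancy
# but the slowest approach, so at NEBD time (~600 s) it is kinetically
# trapped on internal membranes.

library(par2coop)
dir.create("results", showWarnings = FALSE)

# Equilibrium occupancy grid (three compartments, kd_int/kd_mem = 5)
fig5a <- reproduce_model_figures("fig5a", out_dir = "results", fast = FALSE)
cat(sprintf("equilibrium grid: PM:IM ratio spans %.2f - %.2f (written to results/fig5a.csv)\n",
            min(fig5a$pm_im_ratio), max(fig5a$pm_im_ratio)))

# Redistribution trajectories for weak/intermediate/strong dimerization
fig5c <- reproduce_model_figures("fig5c", out_dir = "results", fast = FALSE)

snap <- do.call(rbind, lapply(split(fig5c, fig5c$regime), function(sub) {
  data.frame(regime = sub$regime[1], kd_dim = sub$kd_dim[1],
             f_pm_600s = approx(sub$t, sub$f_pm, 600)$y,
             f_im_600s = approx(sub$t, sub$f_im, 600)$y,
             f_pm_equilibrium = sub$f_pm_equilibrium[1])
}))
snap <- snap[order(-snap$kd_dim), ]
print(snap, row.names = FALSE)
utils::write.csv(snap, "results/trapping_snapshot_600s.csv", row.names = FALSE)

cat("\nNote the inversion: the strong-dimer system has the highest\n")
cat("equilibrium PM fraction but the lowest PM fraction at 600 s, with\n")
cat("protein still held on internal membranes (kinetic trapping).\n")

# Time to half of equilibrium PM loading vs dimer strength
mk <- function(kd_dim, km) {
  model_params(kd_dim, km, 27e-9, psi = 0.087e6,
               kd_int = 5 * 10^-2.43, phi = 0.087e6)
}
t50 <- vapply(c(3.58e-5, 3.58e-6, 3.58e-7, 3.58e-8, 3.58e-9), function(kd) {
  traj <- simulate_symmetry_breaking(mk(kd, 1), mk(kd, 10^-2.43),
                                     lambda_tilde = 4, t_end = 1e7)
  as.numeric(time_to_fraction(traj, 0.5))
}, numeric(1))
tab <- data.frame(kd_dim = c(3.58e-5, 3.58e-6, 3.58e-7, 3.58e-8, 3.58e-9),
                  t_half_s = t50)
print(tab, row.names = FALSE)
utils::write.csv(tab, "results/time_to_half_equilibrium.csv",
                 row.names = FALSE)
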