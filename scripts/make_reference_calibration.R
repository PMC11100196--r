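#!/usr/bin/env Rscript
# Produces the shipped reference calibration committed under
# inst/extdata/: reference_parameters.json and reference_residuals.csv.
#
# Two deterministic stages of gp_calibrate() against the shipped anchor
# file: a broad Latin-hypercube + Nelder-Mead search (seed 42), then a
# warm-started refinement (seed 43). `init0` is the incumbent from an
# earlier exploratory broad search, supplied as one extra start; all
# stages are reproducible from this script alone.
#
#   Rscript scripts/make_reference_calibration.R
#
# (Takes roughly half an hour; the result is committed, so this script
# only needs to be re-run when the model, anchors or bounds change.)

suppressPackageStartupMessages(library(gpdiffuse))

anchors <- read_anchors("inst/extdata/reference_anchors.csv")

free <- c("alpha", "mu", "cr0", "w_wdp", "w_hec", "w_hcs", "w_et",
          "w_jtp", "ii_y1", "ii_d2", "ii_d3", "ii_d4", "w_delta")
lower <- c(alpha = 0.005, mu = 0.01, cr0 = 0.003, w_wdp = 0.02,
           w_hec = 0.02, w_hcs = 0.02, w_et = 0.02, w_jtp = 0.02,
           ii_y1 = 0, ii_d2 = 0, ii_d3 = 0, ii_d4 = 0.001,
           w_delta = 0.505)
upper <- c(alpha = 0.08, mu = 2, cr0 = 0.05, w_wdp = 2.5, w_hec = 2.5,
           w_hcs = 2.5, w_et = 1.2, w_jtp = 1.2, ii_y1 = 0.2,
           ii_d2 = 0.5, ii_d3 = 1.5, ii_d4 = 0.08, w_delta = 0.55)

# incumbent from exploratory screening (documented starting point,
# full precision so the pipeline is exactly reproducible)
init0 <- c(alpha = 0.027556220211604684, mu = 0.060863917673865661,
           cr0 = 0.019546579035200309, w_wdp = 0.8884159838933241,
           w_hec = 0.89999080967001266, w_hcs = 0.89999998608666054,
           w_et = 0.15739707070664449, w_jtp = 0.17076668827800934,
           ii_y1 = 0.02038840157968581, ii_d2 = 0.00038533161581699797,
           ii_d3 = 0.44159589428893181, ii_d4 = 0.0010062746994973471,
           w_delta = 0.50509269432206361)

pen <- function(p) demand_ordering_penalty(p, lambda = 200)

message("stage 1: broad search (seed 42) ...")
stage1 <- gp_calibrate(anchors, free, lower, upper, seed = 42,
                       control = list(n_lhs = 700, n_starts = 6,
                                      maxit = 2000, init = init0),
                       penalty = pen)
message(sprintf("  objective %.4f", stage1$objective))

message("stage 2: warm-started refinement (seed 43) ...")
stage2 <- gp_calibrate(anchors, free, lower, upper, seed = 43,
                       control = list(n_lhs = 150, n_starts = 2,
                                      maxit = 4000, reltol = 1e-11,
                                      init = coef(stage1)),
                       penalty = pen)
message(sprintf("  objective %.4f", stage2$objective))
print(summary(stage2))

p <- stage2$params
lst <- unclass(p)
lst$ii_lookup <- list(x = p$ii_lookup$x, y = p$ii_lookup$y)
lst$delta_scale <- NULL # derived from w_delta and idr_ref
lst$calibration_seed <- stage2$seed
jsonlite::write_json(lst, "inst/extdata/reference_parameters.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
utils::write.csv(stage2$residuals,
                 "inst/extdata/reference_residuals.csv",
                 row.names = FALSE)
message("wrote inst/extdata/reference_parameters.json and ",
        "reference_residuals.csv")
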