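#!/usr/bin/env Rscript
# Benchmark every estimator against synthetic data with known ground truth:
# generate the canonical fixture suite, run the matching estimator on each
# fixture, and tabulate truth vs estimate.

suppressPackageStartupMessages(library(weaklink))

seed <- 1
out_dir <- "results"
fix_dir <- file.path(out_dir, "fixtures")
dir.create(out_dir, showWarnings = FALSE)

truth <- fixture_suite(fix_dir, seed = seed)
message("fixtures written to ", fix_dir)

rows <- list()
add <- function(what, parameter, true, est)
  rows[[length(rows) + 1L]] <<- data.frame(
    dataset = what, parameter = parameter, truth = true, estimate = est,
    rel_error = est / true - 1)

# turbidostat trace -> daily growth estimate
tr <- read_measurements(file.path(fix_dir, "trace.tsv"),
                        required = c("time_h", "od"),
                        numeric_cols = c("time_h", "od"))
trace <- suppressWarnings(
  od_trace(tr$time_h, tr$od, dilution_marks = which(tr$dilution == "TRUE")))
day <- summarize_day(per_cycle_rates(trace))
add("trace", "mu_h", truth$trace$mu, day$mu_bar)

# plate-reader curve -> Gompertz parameters
gc <- read_measurements(file.path(fix_dir, "growth_curve.tsv"),
                        required = c("time_h", "od"),
                        numeric_cols = c("time_h", "od"))
gf <- fit_gompertz(gc$time_h, gc$od)
add("growth_curve", "mu_max", truth$growth_curve$mu_max, gf$mu_max)
add("growth_curve", "lag_h", truth$growth_curve$lag, gf$lag)
add("growth_curve", "a_max", truth$growth_curve$a_max, gf$a_max)

# Ct table -> target copy number
cal <- read_measurements(file.path(fix_dir, "ct_calibrator.tsv"),
                         required = c("primer_set", "ct"), numeric_cols = "ct")
sam <- read_measurements(file.path(fix_dir, "ct_sample.tsv"),
                         required = c("primer_set", "ct"), numeric_cols = "ct")
rq <- relative_quantity(cal, sam, as.list(truth$ct_table$efficiencies),
                        "proA", c("gyrB", "icd"))
add("ct_table", "copy_number", truth$ct_table$copy_number, rq$value)

# competition counts -> relative fitness
cp <- read_measurements(file.path(fix_dir, "competition.tsv"),
                        required = c("channel", "timepoint", "count"),
                        numeric_cols = "count")
cnt <- function(ch, tp) cp$count[cp$channel == ch & cp$timepoint == tp]
gens <- truth$competition$mu_ref * truth$competition$hours / log(2)
w <- relative_fitness(cnt("test", "initial"), cnt("ref", "initial"),
                      cnt("test", "final"), cnt("ref", "final"), gens)
add("competition", "w", truth$competition$w_true, w$w_raw)

# progress curve -> burst parameters
pc <- read_measurements(file.path(fix_dir, "progress_curve.tsv"),
                        required = c("time_s", "a340"),
                        numeric_cols = c("time_s", "a340"))
fb <- fit_burst(pc$time_s, pc$a340)
add("progress_curve", "slope_m", truth$progress_curve$m, fb$slope_m)
add("progress_curve", "burst_b", truth$progress_curve$b, fb$burst_b)

# initial rates -> Michaelis-Menten parameters
mm <- read_measurements(file.path(fix_dir, "mm_rates.tsv"),
                        required = c("S", "v"), numeric_cols = c("S", "v"))
fm <- fit_michaelis_menten(mm$S, mm$v, truth$mm_rates$enzyme_conc)
add("mm_rates", "kcat_s", truth$mm_rates$kcat, fm$kcat)
add("mm_rates", "km_M", truth$mm_rates$km, fm$km)

# effector titration -> allosteric parameters
al <- read_measurements(file.path(fix_dir, "allosteric_rates.tsv"),
                        required = c("L", "v_over_v0"),
                        numeric_cols = c("L", "v_over_v0"))
fa <- fit_allosteric(al$L, al$v_over_v0)
add("allosteric_rates", "kd_M", truth$allosteric_rates$kd, fa$kd)
add("allosteric_rates", "a", truth$allosteric_rates$a, fa$a)

bench <- do.call(rbind, rows)
write_measurements(bench, file.path(out_dir, "benchmarks.tsv"))
write_manifest(file.path(out_dir, "benchmarks_manifest.json"),
               params = list(fixtures = fix_dir), seed = seed,
               inputs = file.path(fix_dir, "manifest.json"))

message("estimator recovery at default (bench-scale) noise:")
print(transform(bench, rel_error = sprintf("%+.2f%%", 100 * rel_error)),
      row.names = FALSE)
message("largest absolute relative error: ",
        sprintf("%.2f%%", 100 * max(abs(bench$rel_error))))
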