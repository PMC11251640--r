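# Shared survey-season definition for the analysis scripts.
#
# Six surveys over four sites: two rocky, two sandy, at the areal scale of
# real herds; land counts biased high at rocky cliff sites (obstructed
# view forces generous extrapolation) and low on open sandy beaches
# (visual approximation misses animals).

season_config <- function(out_dir = "results/pipeline") {
  scenarios <- list(
    list(site_id = "rocky_cliffs_a", terrain = "rocky_type",
         outline_shape = "blob", outline_area = 25000, land_bias = 1.3,
         seed = 101, survey_date = "2018-09-12"),
    list(site_id = "rocky_cliffs_a", terrain = "rocky_type",
         outline_shape = "blob", outline_area = 32000, land_bias = 1.3,
         seed = 102, survey_date = "2018-10-02"),
    list(site_id = "rocky_island_b", terrain = "rocky_type",
         outline_shape = "blob", outline_area = 18000, land_bias = 1.2,
         seed = 103, survey_date = "2018-09-20"),
    list(site_id = "sandy_beach_c", terrain = "sandy_type",
         outline_shape = "blob", outline_area = 40000, land_bias = 0.6,
         seed = 104, survey_date = "2018-09-14"),
    list(site_id = "sandy_beach_c", terrain = "sandy_type",
         outline_shape = "blob", outline_area = 52000, land_bias = 0.6,
         seed = 105, survey_date = "2018-10-05"),
    list(site_id = "sandy_spit_d", terrain = "sandy_type",
         outline_shape = "blob", outline_area = 30000, land_bias = 0.85,
         seed = 106, survey_date = "2018-09-25")
  )
  pipeline_config(scenarios, cell_size = 19.68, fraction = 0.30,
                  n_sims = 10000L, seed = 2018L, out_dir = out_dir)
}
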