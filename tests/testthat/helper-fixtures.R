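# Small in-code fixtures shared across test files.

# clonogenic table with exact pooled PE 0.5 and known per-condition SFs
make_clonogenic_fixture <- function() {
  data.frame(
    radiation_gy = c(0, 0, 4, 0, 4),
    drug_um      = c(0, 0, 0, 75, 75),
    cells_plated = c(200, 200, 200, 200, 200),
    colonies     = c(90, 110, 26, 50, 6),
    replicate    = c(1, 2, 1, 1, 1)
  )
}

# one caliper trajectory crossing `threshold` exactly at `day_cross`
make_trajectory <- function(animal_id, group, day_cross, threshold = 400) {
  data.frame(animal_id = animal_id, group = group,
             day = c(0, day_cross),
             volume_mm3 = c(100, threshold))
}

# caliper table whose group mean growth times are exactly 9/12/16/25 days
make_growth_fixture <- function(n_per_group = 6) {
  times <- c(control = 9, drug = 12, radiation = 16, combination = 25)
  do.call(rbind, lapply(names(times), function(g)
    do.call(rbind, lapply(seq_len(n_per_group), function(i)
      make_trajectory(sprintf("%s_%d", g, i), g, times[[g]])))))
}

# caliper table with constant volumes per group at a single evaluation day
make_volume_fixture <- function(volumes = c(control = 2200, radiation = 1000,
                                            drug = 1500, combination = 490),
                                day = 26, n_per_group = 6) {
  do.call(rbind, lapply(names(volumes), function(g)
    do.call(rbind, lapply(seq_len(n_per_group), function(i)
      data.frame(animal_id = sprintf("%s_%d", g, i), group = g,
                 day = c(0, day), volume_mm3 = c(100, volumes[[g]]))))))
}

printed_cfg <- function() run_config(precision_mode = "printed")
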