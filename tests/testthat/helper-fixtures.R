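# shared fixtures: standard oocyte, baths, and hand-built trajectories

std_geom <- function() oocyte_geometry(0.12)

sucrose_bath <- function(mosm = 1460) bath_solution(mosm)

eg_bath <- function(conc = 1.3, mosm = 200)
  bath_solution(mosm, conc, "ethylene_glycol")

# exactly linear relative-volume trajectory: rel = 1 + slope * t
linear_traj <- function(slope, times = seq(0, 1, by = 0.05),
                        V0 = std_geom()$V0)
  volume_trajectory(times, 1 + slope * times, V0)

# membrane parameters generating the worked shrink-swell example
t85a_eg_params <- function() kk_parameters(2.64, 25.49e-3, 0.8)
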