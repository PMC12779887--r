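# goosesim default configuration.
# Species blocks override the built-in registry; values below restate the
# full default parameter table so this file is a complete, editable record
# of the study conditions.
#
# NOTE on b2: the four bite-mass cap coefficients are provisional; the
# published table typography runs the values together and the parse below
# (7 / 6 / 102 / 129) is a documented choice. Under the default functional
# response the cap rarely binds. h_access (sward accessibility scale, m)
# is a model default, not a literature value; see the methods vignette.
species:
  BAG:
    flight_speed: 19.0
    fmr: 9.84
    b1: 0.33
    b2: 7
    c_handling: 1.0
    t_crop: 0.48
    r_chew: 0.02
    i_max: 0.005
    rmr: 7.25
    flight_mr: 60.80
    initial_weight: 1771
    min_weight: 1080
    max_additional: 600
    max_population: 500000
    flock_size: 1000
    n_sites: 61
    a1: -2.17
    c1: 0.20
    c2: 0.52
    crw_lambda: 0.08
    crw_mu: 1.74
    crw_xmax: 200
    crw_pbw: 0.32
    h_access: 0.03
  GLG:
    flight_speed: 19.2
    fmr: 17.14
    b1: 0.25
    b2: 6
    c_handling: 0.0
    t_crop: 0.80
    r_chew: 0.08
    i_max: 0.02
    rmr: 12.63
    flight_mr: 123.70
    initial_weight: 3401
    min_weight: 2040
    max_additional: 900
    max_population: 70000
    flock_size: 100
    n_sites: 65
    a1: -2.19
    c1: 0.25
    c2: 0.52
    crw_lambda: 0.116
    crw_mu: 2.08
    crw_xmax: 84
    crw_pbw: 0.46
    h_access: 0.25
  PFG:
    flight_speed: 18.8
    fmr: 16.51
    b1: 0.23
    b2: 102
    c_handling: 0.5
    t_crop: 0.59
    r_chew: 0.04
    i_max: 0.009
    rmr: 12.17
    flight_mr: 97.70
    initial_weight: 2170
    min_weight: 1600
    max_additional: 600
    max_population: 15000
    flock_size: 200
    n_sites: 9
    a1: -1.41
    c1: 0.18
    c2: 0.48
    crw_lambda: 0.052
    crw_mu: 2.25
    crw_xmax: 200
    crw_pbw: 0.4
    h_access: 0.10
  WFG:
    flight_speed: 15.0
    fmr: 13.97
    b1: 0.25
    b2: 129
    c_handling: 0.5
    t_crop: 0.59
    r_chew: 0.03
    i_max: 0.008
    rmr: 10.29
    flight_mr: 76.10
    initial_weight: 2127
    min_weight: 1400
    max_additional: 400
    max_population: 300000
    flock_size: 400
    n_sites: 59
    a1: -2.17
    c1: 0.57
    c2: 0.44
    crw_lambda: 0.05
    crw_mu: 1.64
    crw_xmax: 200
    crw_pbw: 0.18
    h_access: 0.10
behaviour:
  p_max_memory: 0.9
  p_max_forage: 0.9
  lambda_memory: 0.2
  memory_size: 100
  beta_join: 2.0
  join_radius: 10
  disturbance:
    scaring: 0.3
    accommodation: 0.02
    nature: 0.02
  moonlight_threshold: 0.5
  night_rest_hours: 8
  max_relocations: 3
energetics:
  e_grass: 17800      # J per g dry matter
  q_assim: 0.35
  e_tissue: 34300     # J per g body reserve
economics:
  price_per_kg: 0.25          # EUR
  dm_per_cm_ha: 150           # kg per cm per ha
  cost_per_scare: 10          # EUR
  cost_per_appraised_patch: 0 # EUR
grass:
  g_max: 0.15    # cm/day
  t_base: 5      # deg C
  t_opt: 18
  r_ref: 15      # MJ m-2 day-1
  ghdgg_enabled: false
  h_opt: 0.07    # m (GHDGG peak)
  ghdgg_width: 0.08
latitude: 53.2
start_doy: 305   # November 1
n_days: 195      # through May 15
population_scalars:
  BAG: 1.0
  GLG: 1.0
  PFG: 1.0
  WFG: 1.0
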