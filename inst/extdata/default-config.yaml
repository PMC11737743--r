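# Default session configuration: the experimental constants of the
# hidden-target shaping task plus the calibrated synthetic-agent defaults.
screen:
  width: 1920
  height: 1080
shaping:
  r_init: 400
  r_target: 100
  n_max: 10
  arms:
    concave_up: -0.3
    linear: 0.0
    concave_down: 0.3
trials:
  n_participants: 54
  trials_per_function: 15
  max_clicks: 50
  consec_stop: 10
agent:
  kind: win_stay_shift
  sigma_exploit: 250
  shrink: 0.7
  grow: 1.05
  lapse: 0.02
  spread_min: 8
  spread_cap: 500
  skill_sd: 0.6
metrics:
  span: 0.4
  degree: 2
  rule: trapezoid
seed: 20190503
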