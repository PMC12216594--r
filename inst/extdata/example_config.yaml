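# Example analysis configuration. Any key may be omitted; omitted keys take
# the documented run_config() defaults.
vel_ceiling_dps: 60      # slow-phase velocity ceiling, deg/s
acc_ceiling_dps2: 1500   # slow-phase acceleration ceiling, deg/s^2
min_segment_ms: 50       # minimum slow-segment duration, ms
bag_resamples: 200       # bootstrap resamples for the velocity profile
dom_threshold_dps: 5     # dominance CI threshold, deg/s
rpd_window_ms: 1500      # RPD window over unmixed perception, ms
mixed_cutoff: 0.70       # trial invalid unless mixed fraction < cutoff
min_valid_trials: 4      # valid trials needed per condition RPD
min_valid_baseline: 3    # valid baseline trials needed for the ODI
odi_cutoff: 0.25         # exclude participants with ODI above this
seed: 1
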