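# Example scenario configuration for the canopyfsp CLI.
# Scenario 2: a 10x10 monoculture at 2.5 cm spacing invaded by 16 weak-SAS
# competitors, canopy hyponasty 5 deg/day, reduced ray budget.
scenario: 2
hyponasty_rate: 5
n_stands: 2
days: 44
nx: 10
ny: 10
spacing: 0.025
n_competitors: 16
competitor_delay: 3
master_seed: 1
source:
  par: 220
  r_fr: 2.3
  angular_model: overcast-diffuse
  n_rays: 20000
growth:
  photoperiod_h: 9
  lue: 1800
  plastochron_days: 1.5
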