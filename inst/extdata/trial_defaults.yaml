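# Default synthetic-trial configuration: a three-arm (control / training /
# training-detraining) 40-week design with group sizes 21/14/14, three
# assessment timepoints (baseline, week 20, week 40) and four training
# phases.  All distributional targets are group-level means and SDs of the
# emulated study population; per-group per-timepoint outcome targets come
# from the longitudinal assessment table.
version: 1
design:
  groups: {C: 21, TR: 14, TRD: 14}
  timepoints: [baseline, wk20, wk40]
  weeks_total: 40
  sessions_per_week: 3
  icc: 0.7          # within-subject correlation via random intercepts
  truncation_sd: 3  # baseline draws truncated at +/- 3 SD
inclusion:
  bmi_window: [25.1, 34.9]
baseline:           # per-group [mean, sd]
  age:          {C: [36.0, 4.2],  TR: [36.4, 5.0],  TRD: [36.9, 4.3]}
  height_m:     {C: [1.65, 0.05], TR: [1.66, 0.05], TRD: [1.64, 0.06]}
  resting_hr:   {C: [70, 7],      TR: [70, 7],      TRD: [70, 7]}   # assumed
  resting_rer:  {C: [0.85, 0.03], TR: [0.85, 0.03], TRD: [0.85, 0.03]}
phases:             # monitored-session physiology per training phase
  - phase: 1
    mean_hr: [118.5, 9.2]
    max_hr: [150.7, 12.2]
    lactate_pre: [1.61, 0.41]
    lactate_mid: [8.02, 0.90]
    lactate_post: [8.99, 1.09]
    ve: [55.71, 6.9]
    vo2: [18.05, 1.9]
    rer: [1.04, 0.06]
    rpe: [13.71, 1.0]
    epoc_kcal: [11.0, 2.8]
  - phase: 2
    mean_hr: [130.8, 12.6]
    max_hr: [157.6, 11.8]
    lactate_pre: [1.54, 0.25]
    lactate_mid: [11.57, 0.72]
    lactate_post: [11.31, 0.77]
    ve: [62.00, 7.0]
    vo2: [19.26, 1.9]
    rer: [1.08, 0.05]
    rpe: [14.86, 0.9]
    epoc_kcal: [26.1, 4.6]
  - phase: 3
    mean_hr: [143.2, 12.1]
    max_hr: [164.9, 11.6]
    lactate_pre: [1.36, 0.33]
    lactate_mid: [12.31, 1.63]
    lactate_post: [11.78, 1.94]
    ve: [68.71, 5.9]
    vo2: [23.64, 2.0]
    rer: [1.10, 0.06]
    rpe: [16.00, 0.9]
    epoc_kcal: [34.7, 3.4]
  - phase: 4
    mean_hr: [151.1, 11.3]
    max_hr: [172.5, 9.9]
    lactate_pre: [1.53, 0.40]
    lactate_mid: [12.42, 1.40]
    lactate_post: [11.99, 1.40]
    ve: [73.50, 5.5]
    vo2: [23.84, 2.4]
    rer: [1.11, 0.07]
    rpe: [16.14, 0.5]
    epoc_kcal: [35.3, 3.8]
activity:           # habitual-activity targets, per group per timepoint
  steps:
    C:   [6399.7, 6370.4, 6351.0]
    TR:  [6330.7, 6363.9, 6536.8]
    TRD: [6870.0, 6933.7, 6748.5]
  steps_sd: {C: 1851.3, TR: 1279.0, TRD: 2030.6}
  mvpa_min:
    C:   [36.0, 36.8, 35.9]
    TR:  [30.5, 32.7, 36.6]
    TRD: [43.3, 43.9, 39.7]
  mvpa_sd: {C: 13.6, TR: 9.6, TRD: 21.2}
  light_min:
    C:   [198.5, 196.9, 156.0]
    TR:  [179.1, 175.9, 186.0]
    TRD: [191.8, 204.6, 193.6]
intake:             # isocaloric prescription targets, kcal/day
  ei_kcal:
    C:   [1829.9, 1835.4, 1834.1]
    TR:  [1840.5, 1807.4, 1782.9]
    TRD: [1839.6, 1812.4, 1807.2]
  macro_split: {cho: 57.5, pro: 17.5, fat: 25.0}
  day_cv: 0.06      # day-to-day lognormal CV of prescribed intake
outcomes:           # per outcome, per group: mean and sd at the 3 timepoints
  body_mass:
    C:   {mean: [80.2, 80.4, 80.9],  sd: [8.9, 7.7, 7.7]}
    TR:  {mean: [78.0, 74.2, 73.4],  sd: [9.9, 10.3, 10.0]}
    TRD: {mean: [78.2, 75.5, 76.7],  sd: [7.8, 8.2, 9.0]}
  bmi:
    C:   {mean: [29.6, 29.5, 29.9],  sd: [3.0, 2.7, 2.7]}
    TR:  {mean: [28.4, 26.8, 26.5],  sd: [2.8, 2.9, 2.7]}
    TRD: {mean: [29.1, 28.1, 28.6],  sd: [3.0, 3.4, 3.5]}
  body_fat_pct:
    C:   {mean: [46.7, 47.1, 47.7],  sd: [6.5, 6.5, 6.5]}
    TR:  {mean: [47.5, 43.4, 42.0],  sd: [3.2, 4.2, 4.5]}
    TRD: {mean: [46.2, 43.8, 44.8],  sd: [3.9, 5.5, 5.1]}
  fat_mass:
    C:   {mean: [37.4, 37.8, 38.6],  sd: [6.5, 6.2, 6.5]}
    TR:  {mean: [37.3, 32.5, 31.1],  sd: [6.7, 7.1, 6.9]}
    TRD: {mean: [36.3, 33.4, 34.6],  sd: [6.0, 7.1, 7.3]}
  ffm:
    C:   {mean: [42.8, 42.6, 42.3],  sd: [7.2, 6.7, 6.6]}
    TR:  {mean: [40.8, 41.7, 42.3],  sd: [4.1, 4.1, 4.5]}
    TRD: {mean: [41.9, 42.1, 42.1],  sd: [3.2, 3.3, 3.6]}
  waist:
    C:   {mean: [95.9, 96.1, 97.6],  sd: [5.3, 4.8, 5.1]}
    TR:  {mean: [96.7, 90.8, 90.1],  sd: [8.8, 8.1, 8.7]}
    TRD: {mean: [96.4, 89.3, 94.0],  sd: [8.9, 9.0, 9.9]}
  hip:
    C:   {mean: [110.3, 111.0, 112.2], sd: [6.5, 6.1, 5.6]}
    TR:  {mean: [110.9, 108.0, 107.9], sd: [6.5, 7.6, 7.1]}
    TRD: {mean: [110.9, 108.8, 110.0], sd: [7.2, 7.9, 7.1]}
  whr:
    C:   {mean: [0.87, 0.87, 0.87],  sd: [0.04, 0.04, 0.04]}
    TR:  {mean: [0.87, 0.84, 0.83],  sd: [0.04, 0.04, 0.05]}
    TRD: {mean: [0.87, 0.82, 0.85],  sd: [0.06, 0.07, 0.07]}
  rmr:
    C:   {mean: [1501.1, 1507.6, 1523.7], sd: [162.8, 150.9, 141.8]}
    TR:  {mean: [1451.6, 1536.4, 1597.9], sd: [145.4, 158.1, 160.9]}
    TRD: {mean: [1504.1, 1637.9, 1524.9], sd: [220.3, 163.6, 170.7]}
  vo2max:
    C:   {mean: [26.1, 25.8, 25.6],  sd: [3.2, 3.2, 3.1]}
    TR:  {mean: [26.1, 31.8, 33.1],  sd: [4.4, 4.8, 4.8]}
    TRD: {mean: [27.4, 31.6, 29.5],  sd: [3.2, 3.6, 3.3]}
  one_rm:
    C:   {mean: [133.8, 133.3, 135.5], sd: [29.7, 26.1, 27.5]}
    TR:  {mean: [124.6, 143.7, 158.5], sd: [22.4, 26.0, 32.3]}
    TRD: {mean: [131.4, 148.2, 146.9], sd: [18.6, 25.6, 24.6]}
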