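name: desk
n_units: 50
start: "2009-01-01"
end: "2009-12-31"
seed: 1
age_bands: ["all"]
outcome_groups: ["respiratory"]
exposure:
  pollutants: ["no2", "pm10", "pm25", "o3"]
  mean:        {no2: 50.7, pm10: 21.2, pm25: 15.6, o3: 49.9}
  temporal_sd: {no2: 15.4, pm10: 8.8, pm25: 8.2, o3: 18.5}
  spatial_sd:  {no2: 16.3, pm10: 2.6, pm25: 1.2, o3: 4.7}
  unit_noise_frac: 0.1
  seasonal_amplitude: {no2: -6.0, pm10: -2.0, pm25: -2.0, o3: 14.0}
  ar1: 0.7
  log_skew: {no2: 0.7, pm10: 0.7, pm25: 0.7, o3: 0.45}
  temporal_cor:
    - [1.00,  0.55,  0.61, -0.60]
    - [0.55,  1.00,  0.96, -0.19]
    - [0.61,  0.96,  1.00, -0.29]
    - [-0.60, -0.19, -0.29, 1.00]
  spatial_cor:
    - [1.00,  0.70,  0.58, -0.55]
    - [0.70,  1.00,  0.75, -0.83]
    - [0.58,  0.75,  1.00, -0.80]
    - [-0.55, -0.83, -0.80, 1.00]
meteorology:
  temp_mean: 11.0
  temp_sd: 5.7
  temp_amplitude: 7.0
  temp_ar1: 0.8
  hum_mean: 77.2
  hum_sd: 10.1
  hum_amplitude: -5.0
  hum_ar1: 0.5
units:
  pct_elderly_mean: 9.0
  pct_elderly_sd: 4.0
  deprivation_mean: 25.0
  deprivation_sd: 8.0
model:
  pollutant: pm10
  beta_short: 0.002
  beta_long: 0.002
  gamma0: -2.1972246
  theta: 1.5
  sigma_b: 0.2
  weekday: [0.05, 0.02, 0.0, -0.03]
  temp: [0.08, 0.12, 0.05]
  humidity: [0.0, 0.0, 0.0]
  pct_elderly: 0.005
  deprivation: 0.004
  daily_mean:
    respiratory: {"all": 2.95}
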