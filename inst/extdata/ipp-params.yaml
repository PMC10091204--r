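# Synthetic parameterisation of the individualized-precision-prevention
# demonstration composite. The service codes AAA, ALC, ASA, BP, BRE,
# CRC, DIA, DIET, STA, SMO, WEI and LUN are the published letter codes;
# the remaining nine (CER, CHL, DEP, HCV, HIV, IMM, OST, PHY, VIT) are
# invented to fill out the 21-service catalog. Every hazard ratio,
# inclusion criterion, and logistic coefficient below is synthetic:
# the architecture is faithful, the numbers are placeholders.
#
# type: net_benefit -> a dedicated net-benefit estimator submodel
#       detection   -> the detection-gain estimator submodel
#       inline      -> benefit computed directly by the top-level executive
services:
  AAA:
    label: Abdominal aortic aneurysm screening
    type: net_benefit
    hr: 0.97
    criteria:
      - {feature: age, min: 50, max: 79}
      - {feature: smoker_ever, eq: true}
  ALC:
    label: Reducing alcohol use
    type: inline
    mechanism: remove_alcohol_rr
    criteria:
      - {feature: age, min: 18, max: 100}
      - {feature: drinks_per_week, min: 8}
  ASA:
    label: Aspirin use
    type: net_benefit
    hr: 0.96
    background: cvdevent
    criteria:
      - {feature: age, min: 40, max: 70}
      - {feature: diabetes, eq: true}
  BP:
    label: Treating blood pressure
    type: net_benefit
    hr: 0.90
    criteria:
      - {feature: age, min: 18, max: 100}
      - {feature: systolic, min: 130}
  BRE:
    label: Breast cancer screening
    type: net_benefit
    hr: 0.95
    background: breastcancer
    criteria:
      - {feature: gender, eq: Female}
      - {feature: age, min: 40, max: 74}
  CER:
    label: Cervical cancer screening
    type: net_benefit
    hr: 0.97
    criteria:
      - {feature: gender, eq: Female}
      - {feature: age, min: 21, max: 65}
  CHL:
    label: Chlamydia screening
    type: net_benefit
    hr: 0.99
    criteria:
      - {feature: gender, eq: Female}
      - {feature: age, min: 18, max: 64}
      - {feature: sexually_active, eq: true}
  CRC:
    label: Colorectal cancer screening
    type: net_benefit
    hr: 0.94
    background: colorectalcancer
    criteria:
      - {feature: age, min: 45, max: 75}
  DEP:
    label: Depression screening
    type: net_benefit
    hr: 0.98
    background: depression
    criteria:
      - {feature: age, min: 18, max: 100}
      - {feature: phq2, min: 1}
  DIA:
    label: Treating diabetes
    type: net_benefit
    hr: 0.88
    background: diabetesonset
    criteria:
      - {feature: age, min: 18, max: 100}
      - {feature: a1c, min: 6.5}
  DIET:
    label: Diet counseling
    type: inline
    mechanism: diet_rr
    criteria:
      - {feature: age, min: 18, max: 100}
      - {feature: bmi, min: 25}
  HCV:
    label: Hepatitis C screening
    type: net_benefit
    hr: 0.96
    criteria:
      - {feature: age, min: 18, max: 79}
      - {feature: hcv_tested, eq: false}
  HIV:
    label: HIV screening
    type: detection
    hr: 0.60
    p_undiagnosed: 0.15
    criteria:
      - {feature: age, min: 18, max: 65}
      - {feature: hiv_diagnosed, eq: false}
  IMM:
    label: Influenza immunization
    type: net_benefit
    hr: 0.97
    criteria:
      - {feature: age, min: 18, max: 100}
      - {feature: flu_vaccinated, eq: false}
  LUN:
    label: Lung cancer screening
    type: net_benefit
    hr: 0.95
    background: lungcancer
    criteria:
      - {feature: age, min: 50, max: 80}
      - {feature: pack_years, min: 20}
      - {feature: smoking_status, in: [current, former]}
  OST:
    label: Osteoporosis screening
    type: net_benefit
    hr: 0.98
    background: osteoporosis
    criteria:
      - {feature: gender, eq: Female}
      - {feature: age, min: 50, max: 100}
  PHY:
    label: Physical activity counseling
    type: inline
    mechanism: fixed_hr
    hr: 0.97
    criteria:
      - {feature: age, min: 18, max: 100}
      - {feature: exercise_minutes_per_week, max: 149}
  SMO:
    label: Smoking cessation
    type: inline
    mechanism: remove_tobacco_rr
    criteria:
      - {feature: age, min: 18, max: 100}
      - {feature: smoking_status, eq: current}
  STA:
    label: Statin use for cholesterol
    type: net_benefit
    hr: 0.92
    criteria:
      - {feature: age, min: 40, max: 75}
      - {feature: totalcholesterol, min: 200}
  VIT:
    label: Fall-prevention supplementation
    type: net_benefit
    hr: 0.99
    criteria:
      - {feature: age, min: 50, max: 100}
      - {feature: falls_risk, eq: true}
  WEI:
    label: Losing 10 pounds of weight
    type: inline
    mechanism: weight_loss
    criteria:
      - {feature: age, min: 18, max: 100}
      - {feature: bmi, min: 30}

# Logistic background-risk submodels (intercept + named coefficients).
# cardiometabolic is wired under the diet lower-level executive; the
# other seven are direct callees of the top-level executive.
background_models:
  lungcancer:       {intercept: -6.0, coefficients: {pack_years: 0.06, age: 0.02}}
  cvdevent:         {intercept: -7.5, coefficients: {age: 0.05, systolic: 0.01, cvd: 1.2}}
  breastcancer:     {intercept: -6.5, coefficients: {age: 0.04, family_history_breast: 1.0}}
  colorectalcancer: {intercept: -7.0, coefficients: {age: 0.05, family_history_crc: 1.1}}
  diabetesonset:    {intercept: -6.0, coefficients: {a1c: 0.45, bmi: 0.05}}
  osteoporosis:     {intercept: -8.0, coefficients: {age: 0.08}}
  depression:       {intercept: -2.5, coefficients: {phq2: 0.5}}
  cardiometabolic:  {intercept: -5.0, coefficients: {bmi: 0.06, systolic: 0.01}}

# How a background risk scales a service's raw hazard-ratio life gain:
# scale = base + slope * risk (so higher background risk -> larger
# share of the raw gain is attainable).
background_link: {base: 0.25, slope: 0.75}
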