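{
  "id": "ipp/bmicalculator/1.0",
  "title": "BMI Calc",
  "contributors": "Model Stewards",
  "ko_version": "1.0",
  "description": "Calculates BMI"
}
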