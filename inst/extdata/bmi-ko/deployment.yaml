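/bmi:
  post:
    engine: r
    entry: bmi.R
    artifact:
    - bmi.R
    function: bmi
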