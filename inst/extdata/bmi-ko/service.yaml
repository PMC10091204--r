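openapi: 3.0.0
info:
  version: '1.0'
  title: BMI Calc
  license:
    name: GPL-3
servers:
- url: /ipp/bmicalculator/1.0
paths:
  /bmi:
    post:
      summary: Invoke /bmi
      responses:
        '200':
          description: result
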