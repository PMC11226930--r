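# Default feature schema: 5 categorical + 17 numerical variables.
# Numerical ranges are theoretical instrument/code ranges, never estimated
# from data. Age range 22-60 (R=38), clinical-experience band 1-6 (R=5) and
# hospital-size code 1-5 (R=4) reproduce the published worked example of the
# element dissimilarities. stage2: false marks research variables excluded
# from the reduced stage-2 comparison set.
variables:
  - name: sex
    kind: categorical
    codes: ["1", "2"]
  - name: marital_status
    kind: categorical
    codes: ["1", "2", "3"]
  - name: position
    kind: categorical
    codes: ["1", "2", "3"]
  - name: department
    kind: categorical
    codes: ["1", "2", "3", "4", "5"]
  - name: shift_type
    kind: categorical
    codes: ["1", "2", "3", "4"]
  - name: age
    kind: numerical
    min: 22
    max: 60
  - name: hospital_size
    kind: numerical
    min: 1
    max: 5
  - name: clinical_experience
    kind: numerical
    min: 1
    max: 6
  - name: overtime
    kind: numerical
    min: 1
    max: 6
  - name: turnover_intention
    kind: numerical
    min: 0
    max: 10
  - name: job_stress
    kind: numerical
    min: 23
    max: 115
    stage2: false
  - name: stress_response
    kind: numerical
    min: 0
    max: 88
    stage2: false
  - name: coping_total
    kind: numerical
    min: 33
    max: 99
    stage2: false
  - name: coping_problem_solving
    kind: numerical
    min: 11
    max: 33
    stage2: false
  - name: coping_social_support
    kind: numerical
    min: 11
    max: 33
    stage2: false
  - name: coping_avoidance
    kind: numerical
    min: 11
    max: 33
    stage2: false
  - name: burnout_personal
    kind: numerical
    min: 0
    max: 100
    role: burnout_personal
  - name: burnout_work
    kind: numerical
    min: 0
    max: 100
    role: burnout_work
  - name: burnout_client
    kind: numerical
    min: 0
    max: 100
    role: burnout_client
  - name: reserved_1
    kind: numerical
    min: 0
    max: 100
    stage2: false
  - name: reserved_2
    kind: numerical
    min: 0
    max: 100
    stage2: false
  - name: reserved_3
    kind: numerical
    min: 0
    max: 100
    stage2: false
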