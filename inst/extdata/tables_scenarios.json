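{
  "comment": "Scenario encodings of the three canonical worked-example tables. All numeric values are percentages.",
  "scenarios": [
    {"name": "T1 perfect 2nd tester",
     "primary": {"sens": 80, "spec": 90}, "modifier": {"sens": 100, "spec": 100}, "prior": 20},
    {"name": "T1 perfect 1st tester",
     "primary": {"sens": 100, "spec": 100}, "modifier": {"sens": 80, "spec": 90}, "prior": 20},
    {"name": "T1 imperfect 2 testers",
     "primary": {"sens": 70, "spec": 85}, "modifier": {"sens": 80, "spec": 90}, "prior": 20},
    {"name": "T1 ignorant 2nd tester, imperfect 1st",
     "primary": {"sens": 70, "spec": 85}, "modifier": {"sens": 50, "spec": 50}, "prior": 20},
    {"name": "T1 ignorant 2nd tester, perfect 1st",
     "primary": {"sens": 100, "spec": 100}, "modifier": {"sens": 50, "spec": 50}, "prior": 20},

    {"name": "T2 bias 0",
     "primary": {"sens": 80, "spec": 90}, "modifier": {"bias": 0}, "prior": 20},
    {"name": "T2 bias 20",
     "primary": {"sens": 80, "spec": 90}, "modifier": {"bias": 20}, "prior": 20,
     "threshold": 90},
    {"name": "T2 bias 40",
     "primary": {"sens": 80, "spec": 90}, "modifier": {"bias": 40}, "prior": 20},
    {"name": "T2 bias 50",
     "primary": {"sens": 80, "spec": 90}, "modifier": {"bias": 50}, "prior": 20},
    {"name": "T2 bias 60",
     "primary": {"sens": 80, "spec": 90}, "modifier": {"bias": 60}, "prior": 20},
    {"name": "T2 bias 80",
     "primary": {"sens": 80, "spec": 90}, "modifier": {"bias": 80}, "prior": 20},
    {"name": "T2 bias 100",
     "primary": {"sens": 80, "spec": 90}, "modifier": {"bias": 100}, "prior": 20},

    {"name": "T3 unbiased tester",
     "primary": {"sens": 80, "spec": 95}, "modifier": {"bias": 0}, "prior": 50},
    {"name": "T3 biased tester",
     "primary": {"sens": 80, "spec": 95}, "modifier": {"bias": 100}, "prior": 50},
    {"name": "T3 informed tester",
     "primary": {"sens": 80, "spec": 95},
     "modifier": {"tp": 100, "fp": 0, "role": "ignorance"}, "prior": 50},
    {"name": "T3 ignorant tester",
     "primary": {"sens": 80, "spec": 95},
     "modifier": {"tp": 60, "fp": 30, "role": "ignorance"}, "prior": 50}
  ]
}
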