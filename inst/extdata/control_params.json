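[
  {
    "scenario": "no_passive",
    "seed": 101,
    "population": 30,
    "generations": 50,
    "objective_mm": 0.0750750229484998,
    "tuned_on": "opt_sequence (4 targets)",
    "tool": "reacharm::optimize_controls"
  },
  {
    "scenario": "A",
    "seed": 102,
    "population": 30,
    "generations": 50,
    "objective_mm": 0.924679214429675,
    "tuned_on": "opt_sequence (4 targets)",
    "tool": "reacharm::optimize_controls"
  },
  {
    "scenario": "B",
    "seed": 103,
    "population": 20,
    "generations": 30,
    "objective_mm": 1.38428794593541,
    "tuned_on": "opt_sequence (4 targets)",
    "tool": "reacharm::optimize_controls"
  },
  {
    "scenario": "C",
    "seed": 104,
    "population": 20,
    "generations": 30,
    "objective_mm": 1.77782848105563,
    "tuned_on": "opt_sequence (4 targets)",
    "tool": "reacharm::optimize_controls"
  },
  {
    "scenario": "D",
    "seed": 105,
    "population": 20,
    "generations": 30,
    "objective_mm": 2.55448153276905,
    "tuned_on": "opt_sequence (4 targets)",
    "tool": "reacharm::optimize_controls"
  },
  {
    "scenario": "E",
    "seed": 106,
    "population": 20,
    "generations": 30,
    "objective_mm": 2.78551493738376,
    "tuned_on": "opt_sequence (4 targets)",
    "tool": "reacharm::optimize_controls"
  },
  {
    "scenario": "F",
    "seed": 107,
    "population": 20,
    "generations": 30,
    "objective_mm": 3.85659055062896,
    "tuned_on": "opt_sequence (4 targets)",
    "tool": "reacharm::optimize_controls"
  },
  {
    "scenario": "G",
    "seed": 108,
    "population": 20,
    "generations": 30,
    "objective_mm": 6.40200833720198,
    "tuned_on": "opt_sequence (4 targets)",
    "tool": "reacharm::optimize_controls"
  },
  {
    "scenario": "H",
    "seed": 109,
    "population": 20,
    "generations": 30,
    "objective_mm": 7.77593344424726,
    "tuned_on": "opt_sequence (4 targets)",
    "tool": "reacharm::optimize_controls"
  }
]
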