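version: 1.0
tau: 0.25
trial_cv: 0.1
sampling_rate: 200.0
duration: 20.0
conditions:
- condition: 1
  amp_ap: 4.6458726
  amp_ml: 1.6614883
  cutoff_ap: 1.5342364
  cutoff_ml: 2.4513884
- condition: 2
  amp_ap: 5.2261611
  amp_ml: 2.0162305
  cutoff_ap: 1.5601253
  cutoff_ml: 2.2780287
- condition: 3
  amp_ap: 4.9020961
  amp_ml: 2.1631621
  cutoff_ap: 1.5690615
  cutoff_ml: 2.2883277
- condition: 4
  amp_ap: 6.8590433
  amp_ml: 3.9634165
  cutoff_ap: 1.7011092
  cutoff_ml: 1.5768993
- condition: 5
  amp_ap: 7.4423355
  amp_ml: 4.0349915
  cutoff_ap: 1.7176412
  cutoff_ml: 1.5845525
- condition: 6
  amp_ap: 7.4216044
  amp_ml: 3.8863805
  cutoff_ap: 1.6075919
  cutoff_ml: 1.4904166
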