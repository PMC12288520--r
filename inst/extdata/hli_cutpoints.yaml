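# Healthy lifestyle index component cutpoints (editable data, not code).
# Each component is scored 0-4; higher scores are healthier.
#
# Continuous components list 4 strictly increasing breaks defining 5 bins
# (right-open: a value equal to a break falls in the upper bin) and the score
# for each bin in ascending order of the variable. Smoking is scored from
# status: never and former smokers get fixed scores; current smokers are
# binned by cigarettes per day. The alcohol "light" boundary of 6 g
# ethanol/day follows the convention for light-or-no drinking; other bounds
# are round conventional values.
bmi:
  breaks: [22, 24, 26, 30]     # kg/m2
  scores: [4, 3, 2, 1, 0]      # lower BMI healthier
smoking:
  never: 4
  former: 3
  current_breaks: [8, 16]      # cigarettes/day
  current_scores: [2, 1, 0]
alcohol:
  breaks: [6, 12, 24, 60]      # g ethanol/day
  scores: [4, 3, 2, 1, 0]
diet:
  breaks: [3, 5, 7, 9]         # healthy diet score points
  scores: [0, 1, 2, 3, 4]      # higher diet score healthier
activity:
  breaks: [20, 40, 60, 90]     # METs
  scores: [0, 1, 2, 3, 4]
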