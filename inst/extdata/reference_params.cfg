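# Reference parameterization of the consumer-resource models
# (algae-zooplankton values; K and F are the gradient parameters with
# ranges 0-10 and 0-0.3, given here at their analysis defaults K = 10,
# F = 0)
r = 0.5
K = 10
g = 0.4
a = 0.6
l = 0.01
e = 0.6
m = 0.15
F = 0
z = 0.5
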