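# Example run configuration: tilted coleoptile, apical photoception,
# light perpendicular to the initial orientation. Angles in degrees
# (keys flagged _deg); SI units otherwise.
beta = 1.2
gamma = 0.8
nu = 0.6
A0_deg = 30
AP_deg = 120
L = 1.0
Lgz = 1.0
GSA_deg = 0
variant = "ARaC"
t_end = 25.0
nodes = 201

[intensity_law]
kind = "stevens_power"
a = 1.0
b = -0.4
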