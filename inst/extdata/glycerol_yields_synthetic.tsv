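# Shake-flask P3HB production on 10 g/L glycerol, assumed fully consumed.
# The engineered-strain titer (2.99 g/L) is a published measurement.
# The control titer is SYNTHETIC: back-calculated from the published
# control carbon yield of 0.30 (the control titer itself was not printed),
# so this file is a worked data-entry example, not a deposited dataset.
sample	group	role	phb_g_l	glycerol_g_l
control_glycerol	glycerol	control	2.1034	10
nog_glycerol	glycerol	engineered	2.99	10
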