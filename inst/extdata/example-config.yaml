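# Example run configuration: the strong-pump tonic case.
# Any omitted key falls back to its documented default.
parameters:
  I_max: 2
  I_app: 1
integration:
  t_end: 12000
  transient: 2000
  dt: 0.005
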