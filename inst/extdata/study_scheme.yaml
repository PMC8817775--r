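# Attribute scheme of the community-based DOT study. The first level of each
# attribute is the dummy-coding reference; 'columns' names the indicator
# column of each non-reference level.
attributes:
  provider: [Family member, CHW, Expert client]
  location: [Work, Home]
  support: [SMS reminders, Call reminders, Travel vouchers]
columns:
  provider: [c_chw, c_expert]
  location: [l_home]
  support: [s_phcall, s_tvouch]
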