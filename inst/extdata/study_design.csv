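task_id,alt_id,provider,location,support
1,1,CHW,Work,Travel vouchers
1,2,Expert client,Home,Call reminders
1,3,,,
2,1,Family member,Home,SMS reminders
2,2,Expert client,Work,Travel vouchers
2,3,,,
3,1,Family member,Home,SMS reminders
3,2,CHW,Work,Call reminders
3,3,,,
4,1,Expert client,Home,SMS reminders
4,2,Family member,Home,Call reminders
4,3,,,
5,1,Family member,Home,Travel vouchers
5,2,CHW,Home,SMS reminders
5,3,,,
6,1,CHW,Work,SMS reminders
6,2,Expert client,Home,Travel vouchers
6,3,,,
7,1,Expert client,Work,SMS reminders
7,2,CHW,Home,Call reminders
7,3,,,
8,1,Expert client,Work,Call reminders
8,2,CHW,Home,Travel vouchers
8,3,,,
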