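cell_cycle	proliferation and cell-cycle progression	Rrm2	E2f7	E2f8	Plk1	Mcm3	Cdc7	Cdc25a
chromatin	chromatin modification	Hdac11	Ezh1	Hdac1	Hdac2	Hdac4
migration	cell migration	Zeb1	Zeb2	Twist1	Cdh1
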