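chrY	14500000	15500000	ctrl
chrY	22900000	23130000	blue
chrY	23140000	23300000	teal
chrY	23310000	23470000	teal
chrY	23480000	23710000	blue
chrY	23720000	23840000	green
chrY	23850000	24100000	red
chrY	24110000	24360000	red
chrY	24370000	24480000	gray
chrY	24490000	24720000	blue
chrY	24730000	24880000	yellow
chrY	24890000	25010000	green
chrY	25020000	25270000	red
chrY	25280000	25530000	red
chrY	25540000	25660000	green
chrY	25670000	25900000	blue
chrY	25910000	26020000	gray
chrY	26030000	26180000	yellow
chrY	26190000	26250000	ir1
chrY	26260000	26320000	ir1
chrY	26330000	26390000	ir2
chrY	26400000	26460000	ir2
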