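partition	total	constant	variable
whole_matrix	82782	47211	35571
pos1	27594	20421	7173
pos2	27594	23114	4480
pos3	27594	3676	23918
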