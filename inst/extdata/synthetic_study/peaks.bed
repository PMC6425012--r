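chr2	144	315
chr2	2571	2683
chr2	3240	3773
chr2	4593	5120
chr2	6775	7212
chr2	8697	8859
chr2	8911	9476
chr2	14062	14486
chr2	14863	15243
chr2	22544	22797
chr2	23945	24384
chr2	29100	29194
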