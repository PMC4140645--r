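((((((((human:7,chimp:7)hominini:2,gorilla:9)homininae:7,orangutan:16)hominidae:13,macaque:29)catarrhini:14,marmoset:43)simiiformes:31,bushbaby:74)primates:16,mouse:90)euarchontoglires:10,(dog:80,cow:80)laurasiatheria:20)root;
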