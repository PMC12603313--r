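>AtTIR1_synthetic synthetic TIR1/AFB reference (planted pocket and AC residues, AtTIR1 numbering)
MDYESQSLHEDDAYHAPMRFSMHDYAEDIMYGMGDIFHPSHNLWCELQVKGPSGYLWPASKIYNMMVKEENSWMYVNMAFFLEKQLVNVNMQDIEGQEFMDCHQFISNEEQVEFWSKSKLDMVAWCIQGYSFGSNKGKYTNHWIIYRLQWLRDAGPWAAGLQFESSFTKQARIHCGFDKYCNNLTHREVCNTGDNSICVLNGYDNTLDREKPFYNIGPEKCERWEDCKPHSKGWPHWPTIMVCQQYPMLIQGSNTDWPIFTWSQPMGDQMKIPVRMDEYTEIHAKPRMIYICHQTTKWGLQIQAIPRNFGQNFENTTENALRNRMKEMAQKVDARGRTFVAGIPLWPTIECPKCPDCHMVNEQWCPGSAGAVIIPNNNLVNVRERHPGLHSGCYVGPHGQGCMACSIYIKGEKVRGRPRCKEADRDVMTYVFDPSFPSLSGFNIATSLRAWPADCNMNADDSEAFQENMAELMRPFSSPAVAVGSSWARMEAIKHAGALAFNDHTASLFERGAVDREYPPTRISIRMNMNPFVSYGTHFQTRRHREMHWWLHDVFMFPRKQYCRMDVTSPQASFAFYSCFIWKYWYADAGWIRD
>ArfRef_synthetic synthetic ARF reference (planted B3 motif, DD span, PB1 lysine and OPCA)
MMAFEKMQTMCSSFEKAPLSIEPYLDDKHMMATIASNSLIWVDGNKGIGYCDYERTYDCLVTNMMTASYPASCGKRNDGALQWGDGHRRNWWVERLPWGLCHFEKFFMTCAYWQVLDIHWCCSNESPLDPWLMPCNFEDETTFTMHEVRSKVQCHGYKSFHRFQCVTPLEQNINQAAFQWMIGFSDDGVMMHSDIECRHGYGEWSIMDVLTDQRKVCYQDPAVVNTGFAMFDVWSACDQKYAKTQKAHFYKYLAWVETVTMFAVMGPDMAYGIWGCVGRKCNPVVWNQMCYWTFNRFTACELSSAGDPSLYQTQYTVTSNKMAHASAASWSSVWPGYIDTDSYRRGNQAAARTDPKPNTYCNYPHIIINAFFCWHQVNVANHRLFATIEHTCAQGFGQCHTSRSPNAHLPAVRSGPNNANAVCTAHMKYSGRHARVWDWQWNRQMNHRNTWPMTFFYNCNPHMAHDDEFEFHGMSTTATLWLNPAKQVTVYSRASQRVNRIYPAFWGFHFTSRTHEPPFMCQTIVGEHKYAWNYKVARLRVPHCYMMLHIKSWPHTRCWNIGSPCMTIHEKRPLHKTKWKGAMIQGADEERLGNNVPFWWECKHQCASLGLDGNEVTGSWCRIQDAELDYASCICAAVFCHGILKRESDSVWYLTTLNGCQGLEESMTHDGASHRQVANVVETNEFFHYMEKCDKRFSMK
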