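>synthetic_chicken_GSDMA taxon=Gallus_gallus_synthetic;clade=bird
WRFGNNFHDAMPGAWKFLLMLTDCKWWSEMILDCHVSVLFHASAFAALMFCKQGWEASRG
RWINLGQDMAQCHMTMPVKIGCQTQFVPHMETWYQLACRMRKGVWSFSASPSSDIPDWQN
EWKCHVYIVEQPDPMDCTCEISTWQLHDGALRKQGKCNFRSTLLNNQGEGLCMPPVRRYQ
NRVTDLVILQHCWDDIIDYGCCKRCGHCSGIGNHTSDSWGPQIIWTLGWWYKHHRMAWQI
FASDGPCYLCIGFKWQLLQKDPAISFHNQEVSNHTQAPTCHTPVFCWHGQDTGLTNQANG
PWMSMMPWADNFCYWQNLAIGLAHHARCFKVATNDYCMMTYSQSDCYTKTKYNETISGHP
DNFMFCRNYAVDYDAAYSNYQIMDFQNQFIPEWNRFGSHCGKHVYKIKMKWFNVMIHALM
NSTIDWKTGG
>synthetic_human_GSDMD taxon=Homo_sapiens_synthetic;clade=mammal
MWKYAIHRRWAVKAWGKNNWDNPWRYFMDPVYYGLLKNGFYGTVHYHMSAEKCMQFWANS
QGAHFALCVIYKVEPAQEGAKSCVEALDAQIQYYYCGDNPRWMDCEYEIGSGKALMECCY
RVFGENIGHGCYKAQNGLKPADIEMSWAGQKIHENQMQWVCSFCVKVSERGQSYNATANE
HQYNLWCDVSHNIPVWTRPSDGEHWADLYWHARNDFNQVANMWWWQEMKRNRDMNYRCLC
WTWNGYNRCWRDMWRNTNWLSYVYHPFLFWGFLTDAMTKFSSAEKVRLQSYWPPTSFELN
GVDFVEKCIVYLEKIKETHSGFQCSAEAQTPAYWGSSECSDYDKHEVPMNDSMWTGTKGR
CRLNKWWVFRHMDKHGVQTNWCKRQKAGEWADHTIVTRKDWPDRIEVETWEYKFSDVSVW
DLDFEEWIRLWVQAYTAHGGAGTLGKIIRRELMTPSQQMAKICHDYVWQMAFHKETQRCN
GFGN
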