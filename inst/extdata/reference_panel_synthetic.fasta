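>PhGlp_syn subfamily=Glp synthetic=true
EAFQEGVGSKMYSECGALEIEMMENFSWFVTGACHPSRYSKYDTAGIGMKMPLAVWGLAPQILQLWNVVSPKFGASFYAQIMSPKGRHNFGSSILGNPAAVQALFFLAFSLLGPLIPSCLDQYIVANNALFWRDHVTFIYYRKLGFDHYHTGLERWQSLRTSRAPWWKSMLHEENVISGGFKSEFLSAYANRRQLKLGAFGLWWGPILVAVTNPARNSKFVVALTRLHIHRLVRQMGIPWTVRINDNCDVFFPTHNGFVKSNRTVSWRSKNWQRTIIERTHQYAKPMLLLQIRAPGFPII
>BgAqp_syn subfamily=Prip synthetic=true
SSVFPKMYFSLGADQYEKMENVSDFVTGACHPSCPIKEDTALYGVLSVAALTGLASFISQLYTVVSWGMGASFYAQIGCPMNPRTHFSSILGNPAAVNALKFLFFSLEGPLIMSGLDVYIVKRNAGFAIYHLTFIYYTKLVFNHGGWGLEMGQVIQHDTAVITLSMWDEHGVHSGGGLSLDLSEPASTAPLTMDAFHLWIGHLLVAVTNPARNSKFVVAPTREAIHRIQAQVDIAWSPYGNANTFVEFPVENGFVKSLIFCSQLSKRWDSTSINRLQDTEKNFLKLFYRLTGSPII
>DmDrip_syn subfamily=Drip synthetic=true
DAFKSSVFPKHYFSLGAPQEVKMQRVSVFVTGACHPKLPIKEDLHLYGHLLVAAVGGHKTFILQLYCKVSTGFGASFYAQIPVPFGYRTHFSSILGNPAAVQALKPLAFSLLGPLPGNLLDVEIVKRPALFAVDTLCFIYYGPLEMPHTPTGLSRMQVDQLYRAVITKSMWHEAKVISGGFISRQLFNSASTAALTHGAFHLWAGTLLVAVTNPARNSKRVVALTKLAWHNIVRQGDINWTPRYNDTMFVMFPVENGFVKSLKFVSLLSKKWDKTSIMRGSFTAPNAFKLFIRMQHSFIE
>PvAqp2_syn subfamily=Eglp synthetic=true
DFVTGACHPSGPIKEDTALLGVLGVAAVTGYASFILQNSTVVYTGFGASFYAIISSPMDYRTHFSSALGNPAAVSDLKFLAFSLWIPLIGSGLDAFIVKRNHLFESDSEYWIYGGKLEFAHLQTGLERIQVIQLSRMVFTLSMPHEYKVISAGDGSLFAYNWASTAANTLGAFALWAGTLLVAVTNPARNSFFVVALFRLAIHRIVRITRHSLSGRINDTTPVMYPVENGFVKSLIFKSNLWKNWDPTSDNRTSRTARPASKLNMRLPESPQI
>DmBib_syn subfamily=Bib synthetic=true
IAGQHDVFPKWEKELCADQIAKMENSMDFVTGALKPSDPYKEWTAIYGVGGQAATTLQRSDILQNLWVTSTGFGASFYAQQFSPQGYRTHFSSILGNPAAVWALVFLMFSKLGPLDPSGLDVYIVIRGALRAVDHLTFAYYCGLEQIHLPTGLQREQVIQLSRAYNTLYNWNEAKVISGTFISLKLSNSGSTADLVLGAFELWAHKLLVAVTNPARNSKFVMTATDLKMHLSVDQWGISWIFKCNDTTYVMFPFENGFVKSDIFVGRENKNWDSFCIYGTSITQKPAMVRFGRLPASPYI
>HsAqp12L_syn subfamily=Aqp12like synthetic=true
QRFWMSVFAKMYFSFGADQITNMLGVSDFVTGACAPAVWIHHDTALCGVYMLAAVVGLASFILQLYIVGIPGYGASFYACISSPMGKSTNMYSILGNPAAVQDWTSLAFHDLPPLIMVGLKSGQVERNALFWKMHDTFIYYGTLDFYYLPTGYNRRQPICLVRHVYAAMNANEAKVPSGGPCCFWLYTHAQTAALTLPAFCLWAGCLLVAVTNPARNSAFVQELTRLAEHRWKRQGGVSWWNDWNDTTFIMKPVENGFVKSPIFKSLQSKLTDSTSINVESRTAKPALNWKARLPGYPII
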