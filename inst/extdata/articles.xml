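<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>6000001</PMID>
      <Article>
        <ArticleTitle>Regional networks of reperfusion care after myocardial infarction</ArticleTitle>
        <Journal>
          <JournalIssue>
            <PubDate>
              <Year>2017</Year>
              <Month>June</Month>
              <Day>2</Day>
            </PubDate>
          </JournalIssue>
        </Journal>
        <AuthorList>
          <Author>
            <LastName>Hartley</LastName>
            <ForeName>Jo</ForeName>
            <AffiliationInfo>
              <Affiliation>Institute of Cardiology, University of Leeds, Leeds LS184AB, United Kingdom</Affiliation>
            </AffiliationInfo>
          </Author>
          <Author>
            <LastName>Brandt</LastName>
            <ForeName>Mika</ForeName>
            <AffiliationInfo>
              <Affiliation>Department of Cardiology, Münster, Germany</Affiliation>
            </AffiliationInfo>
          </Author>
          <Author>
            <LastName>Silva</LastName>
            <ForeName>Ana</ForeName>
          </Author>
          <Author>
            <LastName>Okoro</LastName>
            <ForeName>Chi</ForeName>
          </Author>
          <Author>
            <LastName>Leroy</LastName>
            <ForeName>Claire</ForeName>
            <AffiliationInfo>
              <Affiliation>Unité de Cardiologie, Paris, France</Affiliation>
            </AffiliationInfo>
          </Author>
          <Author>
            <LastName>Weber</LastName>
            <ForeName>Lena</ForeName>
            <AffiliationInfo>
              <Affiliation>Klinik für Kardiologie, Berlin, Germany</Affiliation>
            </AffiliationInfo>
          </Author>
        </AuthorList>
      </Article>
      <MeshHeadingList>
        <MeshHeading>
          <DescriptorName>Myocardial Infarction</DescriptorName>
        </MeshHeading>
        <MeshHeading>
          <DescriptorName>Patient Care Team</DescriptorName>
        </MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>6000002</PMID>
      <Article>
        <ArticleTitle>Outcomes of factor VIII prophylaxis: a multicentre registry report</ArticleTitle>
        <Journal>
          <JournalIssue>
            <PubDate>
              <Year>2019</Year>
              <Month>February</Month>
            </PubDate>
          </JournalIssue>
        </Journal>
        <AuthorList>
          <Author>
            <LastName>Nowak</LastName>
            <ForeName>Eli</ForeName>
            <AffiliationInfo>
              <Affiliation>Berlin University Hospital, Berlin, Germany</Affiliation>
            </AffiliationInfo>
          </Author>
          <Author>
            <LastName>Marchand</LastName>
            <ForeName>Luc</ForeName>
            <AffiliationInfo>
              <Affiliation>Paris Reference Centre, Paris, France</Affiliation>
            </AffiliationInfo>
          </Author>
          <Author>
            <LastName>Ricci</LastName>
            <ForeName>Marta</ForeName>
            <AffiliationInfo>
              <Affiliation>Milan Coagulation Institute, Milan, Italy</Affiliation>
            </AffiliationInfo>
          </Author>
        </AuthorList>
      </Article>
      <DataBankList>
        <DataBank>
          <DataBankName>ClinicalTrials.gov</DataBankName>
          <AccessionNumberList>
            <AccessionNumber>NCT01000001</AccessionNumber>
          </AccessionNumberList>
        </DataBank>
      </DataBankList>
      <MeshHeadingList>
        <MeshHeading>
          <DescriptorName>Hemophilia A</DescriptorName>
        </MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
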